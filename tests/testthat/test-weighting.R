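test_that("counts are exact token tallies in corpus order", {
  corpus <- mkftm:::corpus_from_tokens(c("d1", "d2"),
                                       list(c("aa", "aa", "bb"), "bb"))
  dtm <- build_doc_term_matrix(corpus)
  expect_equal(as.numeric(dtm$counts["aa", ]), c(2, 0))
  expect_equal(as.numeric(dtm$counts["bb", ]), c(1, 1))

  single <- build_doc_term_matrix(mkftm:::corpus_from_tokens("d", list("x")))
  expect_equal(as.matrix(single$counts), matrix(1, 1, 1,
                                                dimnames = list("x", "d")))
})

test_that("token mass is conserved: column sums equal document lengths", {
  corpus <- random_corpus(n_docs = 5)
  dtm <- build_doc_term_matrix(corpus)
  expect_equal(unname(Matrix::colSums(dtm$counts)),
               as.numeric(lengths(corpus$tokens)))
  expect_equal(sum(dtm$counts), sum(lengths(corpus$tokens)))
})

test_that("unprocessed corpora are rejected", {
  expect_error(build_doc_term_matrix(mkftm:::new_corpus("0", "raw text")),
               class = "mkftm_state_error")
})

test_that("cosine normalization gives unit-norm document columns", {
  dtm <- dtm_from_counts(rbind(c(3, 1), c(4, 0)))
  w <- cosine_normalize_documents(dtm)
  expect_equal(as.numeric(w$values[, 1]), c(0.6, 0.8))
  expect_equal(as.numeric(w$values[, 2]), c(1, 0))

  set.seed(7)
  big <- dtm_from_counts(matrix(rpois(40, 2) + 1, 10, 4))
  wn <- cosine_normalize_documents(big)
  expect_equal(unname(sqrt(Matrix::colSums(wn$values^2))), rep(1, 4),
               tolerance = 1e-12)
})

test_that("global stats match a brute-force per-entry loop", {
  dtm <- dtm_from_counts(rbind(c(2, 0, 1), c(1, 1, 1)))
  stats <- global_frequency(dtm)
  expect_equal(unname(stats$F_total), c(3, 3))
  expect_equal(unname(stats$df), c(2, 3))
  expect_equal(stats$M, 3)

  set.seed(11)
  counts <- matrix(rpois(200, 0.7), 20, 10)
  counts[1, ] <- counts[1, ] + 1   # no zero row or column
  counts[, colSums(counts) == 0] <- 1
  stats <- global_frequency(dtm_from_counts(counts))
  df_loop <- apply(counts, 1, function(row) sum(row > 0))
  F_loop <- apply(counts, 1, sum)
  expect_equal(unname(stats$df), unname(df_loop))
  expect_equal(unname(stats$F_total), unname(F_loop))
  expect_true(all(stats$df <= stats$F_total))
  expect_true(all(stats$df <= stats$N))
})

test_that("term probabilities row-normalize the counts", {
  dtm <- dtm_from_counts(rbind(c(2, 0, 2), c(5, 0, 0)))
  P <- term_probability(dtm)
  expect_equal(as.numeric(P[1, ]), c(0.5, 0, 0.5))
  expect_equal(as.numeric(P[2, ]), c(1, 0, 0))

  set.seed(3)
  rand <- dtm_from_counts(matrix(rpois(60, 1) + 1, 6, 10))
  expect_equal(unname(Matrix::rowSums(term_probability(rand))), rep(1, 6),
               tolerance = 1e-12)
})

test_that("IDF variants evaluate the closed forms", {
  # N = 4 documents; term df layout chosen so M = 4
  dtm <- dtm_from_counts(rbind(c(1, 0, 0, 0), c(1, 1, 1, 1)))
  stats <- global_frequency(dtm)
  expect_equal(stats$M, 4)
  expect_equal(unname(hybrid_idf(stats)[1]), log(16))  # log(M*N/df), df = 1
  expect_equal(unname(hybrid_idf(stats)[2]), log(4))   # df = N attains max
  expect_equal(unname(probabilistic_idf(stats)[1]), log(3))
  expect_equal(unname(fp_idf(stats)[1]), log(48))      # log(M*N*(N-1)/1)
  expect_equal(fp_idf(stats)[1],
               hybrid_idf(stats)[1] + probabilistic_idf(stats)[1])

  # midpoint: df = N/2 makes the probabilistic component vanish
  mid <- global_frequency(dtm_from_counts(rbind(c(1, 1, 0, 0), c(1, 1, 1, 1))))
  expect_equal(unname(probabilistic_idf(mid)[1]), 0)
})

test_that("df = N is guarded with the 1/(2N) epsilon, staying finite", {
  dtm <- dtm_from_counts(matrix(1, 2, 4))
  stats <- global_frequency(dtm)
  expect_true(all(is.finite(probabilistic_idf(stats))))
  expect_true(all(is.finite(fp_idf(stats))))
  expect_equal(unname(probabilistic_idf(stats)[1]), log((1 / 8) / 4))
})

test_that("fusion weight equals the sum of its components off the boundary", {
  for (seed in 1:5) {
    corpus <- random_corpus(n_docs = 12, vocab = 25, len = 8, seed = seed)
    stats <- global_frequency(build_doc_term_matrix(corpus))
    interior <- stats$df >= 1 & stats$df < stats$N
    expect_true(any(interior))
    expect_equal(fp_idf(stats)[interior],
                 (hybrid_idf(stats) + probabilistic_idf(stats))[interior],
                 tolerance = 1e-10)
  }
})

test_that("fusion weight strictly decreases with document frequency", {
  N <- 20; M <- 19
  df <- 1:(N - 1)
  vals <- log(M * N * (N - df) / df^2)
  expect_true(all(diff(vals) < 0))
})

test_that("weighting multiplies local by floored global, keeping sparsity", {
  dtm <- dtm_from_counts(rbind(c(2, 0), c(1, 1), c(0, 3)))
  none <- apply_weights(dtm, global_scheme = "none")
  expect_equal(as.matrix(none$values), as.matrix(dtm$counts))

  # hand-multiplied oracle: N=2, M=2; df: t1=1, t2=2, t3=1
  # fp: log(2*2*(2-1)/1)=log(4); df=N term floored via eps then max(.,0)
  w <- apply_weights(dtm, global_scheme = "fp_idf")
  expect_equal(as.matrix(w$values),
               as.matrix(dtm$counts) * c(log(4), 0, log(4)),
               ignore_attr = TRUE)
  expect_true(all((as.matrix(w$values) > 0) <= (as.matrix(dtm$counts) > 0)))

  # a term in over half the documents (but under the max) has negative
  # probabilistic weight and must be floored to a zero row
  dtm2 <- dtm_from_counts(rbind(c(1, 1, 1, 0), c(1, 1, 1, 1), c(1, 0, 0, 0)))
  w2 <- apply_weights(dtm2, global_scheme = "prob_idf")
  expect_equal(as.numeric(w2$values[1, ]), rep(0, 4))
  expect_true(all(as.matrix(w2$values) >= 0))
})

test_that("per-document global scope weights each column by its own max df", {
  dtm <- dtm_from_counts(rbind(c(1, 0), c(1, 1), c(0, 2)))
  w <- apply_weights(dtm, global_scheme = "hybrid_idf",
                     global_max_scope = "document")
  # doc 1 contains terms with df {1, 2} -> M_1 = 2; doc 2 likewise
  expect_equal(w$values[1, 1], 1 * log(2 * 2 / 1))
  expect_equal(w$values[2, 1], 1 * log(2 * 2 / 2))
  expect_equal(w$values[3, 2], 2 * log(2 * 2 / 1))
})

test_that("sparse matrices round-trip through MatrixMarket text", {
  corpus <- random_corpus(n_docs = 6, vocab = 12, seed = 5)
  dtm <- build_doc_term_matrix(corpus)
  base <- file.path(withr::local_tempdir(), "dtm")
  write_matrix(dtm, base)
  back <- read_dtm(base)
  expect_equal(as.matrix(back$counts), as.matrix(dtm$counts))
  expect_identical(back$vocabulary, dtm$vocabulary)
  expect_identical(back$doc_ids, dtm$doc_ids)
})
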