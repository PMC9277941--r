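test_that("CH index equals the hand-computed value on the 1-D example", {
  pts <- matrix(c(0, 1, 10, 11), ncol = 1)
  labels <- c("A", "A", "B", "B")
  # between = 2*(0.5-5.5)^2 + 2*(10.5-5.5)^2 = 100; within = 4*0.25 = 1
  # factor = (4-2)/(2-1) = 2
  expect_equal(calinski_harabasz(pts, labels), 200)
})

test_that("CH index handles degenerate scatter cases", {
  singletons <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_identical(calinski_harabasz(rbind(singletons, c(9, 9)),
                                     c("a", "b", "c")), Inf)
  coincident <- matrix(1, 4, 2)
  expect_identical(calinski_harabasz(coincident, c(1, 1, 2, 2)), 0)
  expect_error(calinski_harabasz(matrix(rnorm(6), 3), c(1, 1, 1)),
               class = "mkftm_undefined_index_error")
})

test_that("CH index is invariant to rigid motions and relabeling", {
  set.seed(5)
  pts <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, 4), 10, 2))
  labels <- rep(1:2, each = 10)
  base <- calinski_harabasz(pts, labels)
  theta <- 0.6
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  moved <- pts %*% R + 3
  expect_equal(calinski_harabasz(moved, labels), base, tolerance = 1e-10)
  expect_equal(calinski_harabasz(pts, 3 - labels), base, tolerance = 1e-12)
})

make_model <- function(P_W_given_T, P_T_given_D, vocab, docs) {
  structure(list(K = ncol(P_W_given_T), P_W_given_T = P_W_given_T,
                 P_T_given_D = P_T_given_D, vocabulary = vocab,
                 doc_ids = docs),
            class = "mkftm_topic_model")
}

test_that("log-likelihood matches closed forms and a hand-summed fixture", {
  # certainty: single word, P(w|T) = 1 -> LL ~ count * log(1)
  m1 <- make_model(matrix(1, 1, 1), matrix(1, 1, 1), "w", "d")
  d1 <- dtm_from_counts(matrix(3, 1, 1, dimnames = list("w", "d")))
  expect_equal(corpus_log_likelihood(m1, d1), 3 * log(1 + 1e-12))

  # uniform model over m words -> total_tokens * log(1/m)
  vocab <- c("a", "b", "c")
  counts <- matrix(c(2, 1, 0, 1, 1, 1), 3, 2,
                   dimnames = list(vocab, c("d1", "d2")))
  unif <- make_model(matrix(1 / 3, 3, 2), matrix(0.5, 2, 2), vocab,
                     c("d1", "d2"))
  expect_equal(corpus_log_likelihood(unif, dtm_from_counts(counts)),
               6 * log(1 / 3 + 1e-12))

  # hand-set tables, per-token hand sum
  pwt <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  ptd <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  model <- make_model(pwt, ptd, vocab, c("d1", "d2"))
  mix <- pwt %*% t(ptd)
  hand <- sum(counts * log(mix + 1e-12))
  expect_equal(corpus_log_likelihood(model, dtm_from_counts(counts)), hand)
  expect_lt(hand, 0)
})

test_that("log-likelihood refuses mismatched vocabularies", {
  m <- make_model(matrix(1, 1, 1), matrix(1, 1, 1), "w", "d")
  wrong <- dtm_from_counts(matrix(1, 1, 1, dimnames = list("v", "d")))
  expect_error(corpus_log_likelihood(m, wrong), class = "mkftm_state_error")
})

test_that("planted tables score at least as well as a shuffled model", {
  for (seed in 1:3) {
    set.seed(seed)
    synth <- generate_corpus(recovery_spec(seed))
    dtm <- build_doc_term_matrix(synth$corpus)
    planted <- make_model(
      t(synth$planted_topic_word[, dtm$vocabulary]),
      synth$planted_doc_topic, dtm$vocabulary, dtm$doc_ids)
    scrambled <- make_model(
      t(synth$planted_topic_word[, sample(dtm$vocabulary)]),
      synth$planted_doc_topic, dtm$vocabulary, dtm$doc_ids)
    expect_gt(corpus_log_likelihood(planted, dtm),
              corpus_log_likelihood(scrambled, dtm))
  }
})

test_that("planted tables never score worse than fitted tables beyond noise", {
  for (seed in 1:2) {
    synth <- generate_corpus(recovery_spec(seed))
    dtm <- build_doc_term_matrix(synth$corpus)
    model <- fit_mkftm(synth$corpus, K = 5, mkftm_config(seed = seed))
    planted <- make_model(
      t(synth$planted_topic_word[, dtm$vocabulary]),
      synth$planted_doc_topic, dtm$vocabulary, dtm$doc_ids)
    ll_fit <- corpus_log_likelihood(model, dtm)
    ll_planted <- corpus_log_likelihood(planted, dtm)
    expect_gte(ll_planted, ll_fit - 0.02 * abs(ll_fit))
  }
})

test_that("posterior estimates agree with an independent LDA implementation", {
  set.seed(1)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 2), 50, 2))
  y <- rep(c("a", "b"), each = 50)
  model <- train_discriminant(X, y)
  ours <- posterior_probabilities(model, X)
  ref <- predict(MASS::lda(X, grouping = y))$posterior
  expect_equal(unname(ours), unname(ref), tolerance = 1e-5)
})

test_that("discriminant training recovers class structure", {
  set.seed(8)
  n <- 60
  X <- rbind(matrix(rnorm(2 * n, 0), ncol = 2), matrix(rnorm(2 * n, 3), ncol = 2))
  y <- rep(c("a", "b"), each = n)
  model <- train_discriminant(X, y)
  expect_equal(unname(model$means[1, ]), c(0, 0), tolerance = 3 / sqrt(n))
  expect_equal(unname(model$means[2, ]), c(3, 3), tolerance = 3 / sqrt(n))
  expect_gt(mean(as.character(classify(model, X)) == y), 0.95)

  expect_error(train_discriminant(X, rep("a", 2 * n)),
               class = "mkftm_config_error")
})

test_that("degenerate point-mass classes are separated perfectly", {
  X <- rbind(matrix(0, 3, 2), matrix(1, 3, 2))
  y <- rep(c("zero", "one"), each = 3)
  model <- train_discriminant(X, y)
  expect_equal(as.character(classify(model, X)), y)
})

test_that("zero-one cost reduces to posterior argmax on random posteriors", {
  model <- structure(list(classes = c("c1", "c2", "c3"),
                          cost = 1 - diag(3), d = 3),
                     class = "mkftm_discriminant")
  set.seed(10)
  P <- matrix(rexp(3000), 1000, 3)
  P <- P / rowSums(P)
  pred <- classify(model, posteriors = P)
  brute <- apply(P, 1, function(p) {
    costs <- vapply(1:3, function(y) sum(p * model$cost[y, ]), numeric(1))
    which.min(costs)
  })
  expect_identical(as.integer(pred), brute)
  expect_identical(brute, unname(apply(P, 1, which.max)))
})

test_that("asymmetric costs shift the decision away from expensive errors", {
  model <- structure(list(classes = c("c1", "c2"),
                          cost = rbind(c(0, 10), c(1, 0)), d = 2),
                     class = "mkftm_discriminant")
  # predicting c1 risks 0.5 * 10; predicting c2 risks 0.5 * 1
  pred <- classify(model, posteriors = c(0.5, 0.5))
  expect_identical(as.character(pred), "c2")
})

test_that("cross-validation is stratified, deterministic and calibrated", {
  set.seed(12)
  X <- rbind(matrix(rnorm(60, 0), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 30)
  cv <- cross_validate(X, y, folds = 5, seed = 3)
  expect_equal(cv$accuracy, 1)
  expect_equal(cv$macro_f1, 1)

  again <- cross_validate(X, y, folds = 5, seed = 3)
  expect_identical(cv$predictions, again$predictions)

  # permutation null: shuffled labels score near chance (1/2)
  accs <- vapply(1:10, function(r) {
    set.seed(100 + r)
    cross_validate(X, sample(y), folds = 5, seed = r)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.05 + 3 * sd(accs) / sqrt(10))

  expect_error(cross_validate(X, y, folds = 40, seed = 1),
               class = "mkftm_config_error")
})

test_that("clustering protocol produces a finite CH index on fitted models", {
  synth <- generate_corpus(synthetic_spec(K_true = 3, vocab_size = 60,
                                          n_docs = 40, seed = 2))
  model <- fit_mkftm(synth$corpus, K = 3, mkftm_config(seed = 2))
  km <- evaluate_topic_clustering(model, seed = 1)
  expect_true(is.finite(km$ch_index) || km$ch_index == Inf)
  expect_gt(km$ch_index, 0)
  am <- evaluate_topic_clustering(model, method = "argmax")
  expect_length(am$assignments, length(model$doc_ids))
})

test_that("metric reports are written as JSON plus flat TSV", {
  d <- withr::local_tempdir()
  base <- file.path(d, "metrics")
  write_evaluation(list(ch_index = 12.5, note = "x"), base, K = 3, seed = 1)
  js <- jsonlite::read_json(paste0(base, ".json"))
  expect_equal(js$ch_index, 12.5)
  tsv <- read.delim(paste0(base, ".tsv"))
  expect_identical(tsv$metric, "ch_index")
  expect_equal(tsv$value, 12.5)
})
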