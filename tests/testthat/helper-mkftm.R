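# shared fixtures, built in code

# tiny tokenized corpus with a known vocabulary
tiny_corpus <- function() {
  mkftm:::corpus_from_tokens(
    c("d1", "d2", "d3"),
    list(c("aa", "aa", "bb"), c("bb", "cc"), c("cc", "cc", "dd", "aa")))
}

# random tokenized corpus: every document non-empty, every term used
random_corpus <- function(n_docs = 20, vocab = 30, len = 15, seed = 1) {
  set.seed(seed)
  terms <- sprintf("t%02d", seq_len(vocab))
  toks <- lapply(seq_len(n_docs), function(j) {
    sample(terms, len, replace = TRUE)
  })
  # make sure every term appears at least once
  toks[[1]] <- c(toks[[1]], terms)
  mkftm:::corpus_from_tokens(sprintf("d%02d", seq_len(n_docs)), toks)
}

# an mkftm_dtm from an explicit dense count matrix
dtm_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  vocab <- rownames(counts) %||% sprintf("t%02d", seq_len(nrow(counts)))
  docs <- colnames(counts) %||% sprintf("d%02d", seq_len(ncol(counts)))
  structure(list(counts = Matrix::Matrix(counts, sparse = TRUE,
                                         dimnames = list(vocab, docs)),
                 vocabulary = vocab, doc_ids = docs,
                 N = ncol(counts), m = nrow(counts)),
            class = "mkftm_dtm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated 2-D blobs with planted labels
blob_points <- function(n_per = 20, sep = 8, seed = 42) {
  set.seed(seed)
  pts <- rbind(matrix(rnorm(2 * n_per, 0), ncol = 2),
               matrix(rnorm(2 * n_per, sep), ncol = 2))
  list(points = pts, labels = rep(1:2, each = n_per))
}

# independent single-kernel (kernel) fuzzy c-means, plain loops, used as
# the oracle for the S = 1 reduction of the multiple-kernel algorithm
reference_kfcm <- function(gram, V0, s, tol = 1e-5, max_iter = 100) {
  V <- V0
  B <- nrow(V); F_ <- ncol(V)
  for (l in seq_len(max_iter)) {
    vhat <- matrix(0, B, F_)
    for (f in seq_len(F_)) vhat[, f] <- V[, f]^s / sum(V[, f]^s)
    alpha <- matrix(0, B, F_)
    for (i in seq_len(B)) for (f in seq_len(F_)) {
      acc <- gram[i, i]
      for (j in seq_len(B)) acc <- acc - 2 * vhat[j, f] * gram[i, j]
      for (j in seq_len(B)) for (jp in seq_len(B)) {
        acc <- acc + vhat[j, f] * vhat[jp, f] * gram[j, jp]
      }
      alpha[i, f] <- max(acc, 0)
    }
    T2 <- alpha   # single kernel, z = 1
    V_new <- matrix(0, B, F_)
    for (i in seq_len(B)) {
      if (any(T2[i, ] <= 0)) {
        V_new[i, T2[i, ] <= 0] <- 1 / sum(T2[i, ] <= 0)
      } else {
        for (f in seq_len(F_)) {
          V_new[i, f] <- 1 / sum((T2[i, f] / T2[i, ])^(1 / (s - 1)))
        }
      }
    }
    delta <- sqrt(sum((V_new - V)^2))
    V <- V_new
    if (delta < tol) break
  }
  V
}

# recovery study conditions: sharp, single-topic-dominated documents
recovery_spec <- function(seed, redundancy_rate = 0) {
  synthetic_spec(K_true = 5, vocab_size = 500, n_docs = 200,
                 topic_sharpness = 0.05, doc_topic_concentration = 0.02,
                 redundancy_rate = redundancy_rate, seed = seed)
}
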