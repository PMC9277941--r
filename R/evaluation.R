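#' Calinski-Harabasz cluster validity index
#'
#' The variance-ratio criterion: between-cluster scatter over within-cluster
#' scatter, scaled by (N - K)/(K - 1); higher is better. Squared Euclidean
#' distances are the default, which recovers the classic variance ratio;
#' `squared = FALSE` uses plain Euclidean distances instead. Zero within
#' scatter with positive between scatter yields `Inf`; zero between scatter
#' yields 0.
#'
#' @param points numeric observation matrix (rows = observations).
#' @param labels cluster assignment per observation (>= 2 non-empty
#'   clusters, fewer clusters than observations).
#' @param squared use squared Euclidean distances (default TRUE).
#' @return a single number.
#' @export
calinski_harabasz <- function(points, labels, squared = TRUE) {
  points <- as.matrix(points)
  labels <- as.factor(labels)
  K <- nlevels(labels)
  N <- nrow(points)
  if (K < 2L || any(table(labels) == 0L) || N < K) {
    stop_mkftm("CH index needs 2 <= K <= N with non-empty clusters",
               class = "mkftm_undefined_index_error")
  }
  dfun <- if (squared) function(d2) d2 else sqrt
  grand <- colMeans(points)
  between <- 0; within <- 0
  for (lv in levels(labels)) {
    idx <- labels == lv
    cen <- colMeans(points[idx, , drop = FALSE])
    between <- between + sum(idx) * dfun(sum((cen - grand)^2))
    within <- within +
      sum(dfun(rowSums(sweep(points[idx, , drop = FALSE], 2L, cen)^2)))
  }
  factor <- (N - K) / (K - 1)
  if (within == 0) {
    if (between == 0) return(0)
    return(Inf)
  }
  factor * between / within
}

#' Clustering evaluation protocol on topic features
#'
#' Mirrors the evaluation used for document clustering: hard clusters are
#' obtained from the per-document topic distribution P(T|D), either by
#' seeded k-means on its rows (default) or by taking each document's argmax
#' topic, and scored with the Calinski-Harabasz index.
#'
#' @param model an `mkftm_topic_model`.
#' @param K number of hard clusters (default: the model's topic count).
#' @param method `"kmeans"` or `"argmax"`.
#' @param seed seed for k-means initialization.
#' @return list with `ch_index`, `K`, `assignments`.
#' @export
evaluate_topic_clustering <- function(model, K = model$K,
                                      method = c("kmeans", "argmax"),
                                      seed = 1L) {
  method <- match.arg(method)
  X <- model$P_T_given_D
  assignments <- if (method == "kmeans") {
    with_seed(seed, stats::kmeans(X, centers = K, nstart = 5)$cluster)
  } else {
    hard_assignments(X)
  }
  list(ch_index = calinski_harabasz(X, assignments), K = K,
       assignments = assignments)
}

#' Training-corpus log-likelihood of a topic model
#'
#' Scores the count matrix under the mixture P(w | d) =
#' sum_k P(w | T_k) P(T_k | d):
#' LL = sum_{j} sum_{i} tf_ij log(P(w_i | d_j) + 1e-12). The epsilon keeps
#' the sum finite when a token falls outside the model's support, so the
#' value is always finite and nonpositive whenever the mixture
#' probabilities are at most 1.
#'
#' @param model an `mkftm_topic_model`.
#' @param dtm an `mkftm_dtm` over the same vocabulary and documents.
#' @return a single nonpositive number.
#' @export
corpus_log_likelihood <- function(model, dtm) {
  stopifnot(inherits(model, "mkftm_topic_model"), inherits(dtm, "mkftm_dtm"))
  if (!identical(model$vocabulary, dtm$vocabulary) ||
      !identical(model$doc_ids, dtm$doc_ids)) {
    stop_mkftm("model and matrix vocabulary/documents disagree",
               class = "mkftm_state_error")
  }
  mix <- model$P_W_given_T %*% t(model$P_T_given_D)   # m x n
  tri <- as(as(dtm$counts, "generalMatrix"), "TsparseMatrix")
  sum(tri@x * log(mix[cbind(tri@i + 1L, tri@j + 1L)] + 1e-12))
}

#' Cost-sensitive discriminant classifier on topic features
#'
#' Fits a linear (shared-covariance) Gaussian discriminant model on
#' feature rows — typically the rows of P(T|D) — with empirical class
#' priors and a ridge-regularized pooled covariance
#' (lambda = 1e-6 * trace/dim). Prediction picks the class minimizing the
#' expected cost sum_k p(k | x) C(y | k); with the default 0-1 cost matrix
#' this is the maximum-posterior class, ties going to the lowest class
#' index.
#'
#' @param features numeric matrix, observations in rows.
#' @param labels class label per row (>= 2 classes, each with >= 2
#'   examples).
#' @param cost K x K cost matrix `C[y, k]`, nonnegative with zero
#'   diagonal; default 0-1.
#' @return an `mkftm_discriminant` model.
#' @export
train_discriminant <- function(features, labels, cost = NULL) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  classes <- levels(labels)
  if (length(classes) < 2L) {
    stop_mkftm("need at least 2 classes", class = "mkftm_config_error")
  }
  if (any(table(labels) < 2L)) {
    stop_mkftm("every class needs >= 2 examples", class = "mkftm_config_error")
  }
  d <- ncol(features)
  Kc <- length(classes)
  means <- t(vapply(classes, function(cl) {
    colMeans(features[labels == cl, , drop = FALSE])
  }, numeric(d)))
  priors <- as.numeric(table(labels)) / length(labels)
  centered <- features - means[as.integer(labels), , drop = FALSE]
  sigma <- crossprod(centered) / (nrow(features) - Kc)
  lambda <- 1e-6 * sum(diag(sigma)) / d
  sigma <- sigma + diag(max(lambda, 1e-12), d)
  sigma_inv <- tryCatch(solve(sigma), error = function(e) {
    stop_mkftm("singular covariance after regularization",
               class = "mkftm_numeric_error")
  })
  if (is.null(cost)) {
    cost <- 1 - diag(Kc)
  } else {
    cost <- as.matrix(cost)
    stopifnot(nrow(cost) == Kc, ncol(cost) == Kc,
              all(cost >= 0), all(diag(cost) == 0))
  }
  structure(list(classes = classes, means = means, priors = priors,
                 sigma_inv = sigma_inv, cost = cost, d = d),
            class = "mkftm_discriminant")
}

#' Class posteriors under the discriminant model
#'
#' @param model an `mkftm_discriminant`.
#' @param x numeric matrix of feature rows (or a single vector).
#' @return matrix of posterior probabilities, one row per observation.
#' @export
posterior_probabilities <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stop_mkftm("feature dimension mismatch", class = "mkftm_input_error")
  }
  # log N(x; mu_k, Sigma) + log prior, up to a shared constant
  scores <- vapply(seq_along(model$classes), function(k) {
    diff <- sweep(x, 2L, model$means[k, ])
    -0.5 * rowSums((diff %*% model$sigma_inv) * diff) + log(model$priors[k])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x))
  scores <- scores - apply(scores, 1L, max)
  p <- exp(scores)
  p / rowSums(p)
}

#' Predict classes by minimum expected cost
#'
#' @param model an `mkftm_discriminant`.
#' @param x feature matrix or vector.
#' @param posteriors optionally, precomputed posterior rows (bypasses the
#'   Gaussian model; used to apply the decision rule directly).
#' @return factor of predicted classes.
#' @export
classify <- function(model, x = NULL, posteriors = NULL) {
  if (is.null(posteriors)) posteriors <- posterior_probabilities(model, x)
  if (is.null(dim(posteriors))) posteriors <- matrix(posteriors, nrow = 1)
  expected_cost <- posteriors %*% t(model$cost)    # [obs, y]
  idx <- apply(expected_cost, 1L, which.min)       # ties -> lowest index
  factor(model$classes[idx], levels = model$classes)
}

# seeded stratified fold assignment: shuffle within class, deal round-robin
stratified_folds <- function(labels, folds, seed) {
  labels <- as.factor(labels)
  if (any(table(labels) < folds)) {
    stop_mkftm("every class needs >= `folds` examples",
               class = "mkftm_config_error")
  }
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_of
}

#' Stratified cross-validation of the discriminant classifier
#'
#' Seeded stratified k-fold: each class is shuffled once and dealt
#' round-robin into folds, so splits are deterministic given the seed.
#' Reports accuracy and macro-averaged precision, recall and F1.
#'
#' @param features numeric matrix of feature rows.
#' @param labels class labels.
#' @param folds number of folds (default 10).
#' @param seed shuffle seed.
#' @param cost optional cost matrix passed to [train_discriminant()].
#' @return list: `accuracy`, `macro_precision`, `macro_recall`, `macro_f1`,
#'   `folds`, `seed`, `predictions` (aligned with `labels`).
#' @export
cross_validate <- function(features, labels, folds = 10L, seed = 1L,
                           cost = NULL) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  folds <- as.integer(folds)
  stopifnot(folds >= 2L)
  fold_of <- stratified_folds(labels, folds, seed)
  pred <- factor(rep(NA_character_, length(labels)), levels = levels(labels))
  for (f in seq_len(folds)) {
    test <- fold_of == f
    model <- train_discriminant(features[!test, , drop = FALSE],
                                labels[!test], cost = cost)
    pred[test] <- classify(model, features[test, , drop = FALSE])
  }
  cm <- table(truth = labels, pred = pred)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  list(accuracy = sum(tp) / sum(cm),
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1), folds = folds, seed = seed, predictions = pred)
}

#' Write an evaluation report
#'
#' Emits the metrics both as JSON and as a flat TSV
#' (`metric <TAB> value <TAB> K <TAB> seed`) convenient for aggregating
#' sweeps.
#'
#' @param metrics named list of scalar metrics.
#' @param path base path; `.json` and `.tsv` are appended.
#' @param K,seed run identifiers recorded in each TSV row.
#' @export
write_evaluation <- function(metrics, path, K = NA, seed = NA) {
  jsonlite::write_json(metrics, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  scalars <- metrics[vapply(metrics, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  df <- data.frame(metric = names(scalars),
                   value = as.numeric(unlist(scalars)), K = K, seed = seed)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
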