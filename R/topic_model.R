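#' Document probabilities from the weighted matrix
#'
#' P(D_j) is document j's share of the total global term weight: the j-th
#' column sum of the weighted matrix over the grand total.
#'
#' @param weighted an `mkftm_weighted`.
#' @return numeric vector summing to 1.
#' @export
document_probabilities <- function(weighted) {
  stopifnot(inherits(weighted, "mkftm_weighted"))
  cs <- Matrix::colSums(weighted$values)
  total <- sum(cs)
  if (total <= 0) {
    stop_mkftm("all-zero weighted matrix", class = "mkftm_degenerate_input_error")
  }
  stats::setNames(cs / total, weighted$doc_ids)
}

#' Joint and conditional topic-document distributions
#'
#' The joint is P(D_j, T_k) = P(T_k | D_j) P(D_j); normalizing each topic
#' column of the joint gives P(D_j | T_k). A topic with zero total mass is
#' kept (K is preserved) with a uniform column and a warning.
#'
#' @param P_T_given_D n x K row-stochastic membership matrix.
#' @param P_D length-n document probabilities.
#' @return list with `joint` (n x K) and `P_D_given_T` (n x K,
#'   column-stochastic).
#' @export
topic_document_distribution <- function(P_T_given_D, P_D) {
  P_T_given_D <- as.matrix(P_T_given_D)
  stopifnot(nrow(P_T_given_D) == length(P_D))
  joint <- P_T_given_D * P_D
  mass <- colSums(joint)
  cond <- joint
  for (k in seq_along(mass)) {
    if (mass[k] > 0) {
      cond[, k] <- joint[, k] / mass[k]
    } else {
      warning("degenerate topic ", k, " has zero mass; uniform column kept")
      cond[, k] <- 1 / nrow(joint)
    }
  }
  list(joint = joint, P_D_given_T = cond)
}

#' Word distributions per document
#'
#' Column-normalizes the weighted matrix: P(W_i | D_j) is term i's share of
#' document j's total weight.
#'
#' @param weighted an `mkftm_weighted` with no zero document column.
#' @return m x n column-stochastic matrix.
#' @export
word_document_distribution <- function(weighted) {
  stopifnot(inherits(weighted, "mkftm_weighted"))
  cs <- Matrix::colSums(weighted$values)
  if (any(cs <= 0)) {
    stop_mkftm("zero document column", class = "mkftm_degenerate_input_error")
  }
  P <- as.matrix(weighted$values %*% Matrix::Diagonal(x = 1 / cs))
  dimnames(P) <- list(weighted$vocabulary, weighted$doc_ids)
  P
}

#' Word distributions per topic
#'
#' Mixes document word distributions by each topic's document weights:
#' P(W_i | T_k) = sum_j P(W_i | D_j) P(D_j | T_k). Topic columns inherit
#' normalization from the inputs.
#'
#' @param P_W_given_D m x n column-stochastic matrix.
#' @param P_D_given_T n x K column-stochastic matrix.
#' @return m x K column-stochastic matrix.
#' @export
word_topic_distribution <- function(P_W_given_D, P_D_given_T) {
  if (ncol(P_W_given_D) != nrow(P_D_given_T)) {
    stop_mkftm("document dimensions disagree", class = "mkftm_state_error")
  }
  as.matrix(P_W_given_D) %*% as.matrix(P_D_given_T)
}

#' End-to-end pipeline configuration
#'
#' Bundles every stage's settings with their defaults: preprocessing,
#' weighting schemes, PCA dimensionality, and the fuzzy clustering
#' parameters. One seed drives all randomness.
#'
#' @param preprocess a [preprocess_config()]; ignored for corpora that are
#'   already tokenized.
#' @param local_scheme,global_scheme,global_max_scope weighting options,
#'   see [apply_weights()].
#' @param n_components PCA retention, see [reduce_documents()].
#' @param fuzzifier,tolerance,max_iterations,n_starts,kernels clustering
#'   options, see [mkfcm_config()]. The default fuzzifier is 1.1: document
#'   vectors live in high-dimensional space where relative distance ratios
#'   approach 1, and larger exponents (the low-dimensional convention of 2)
#'   collapse memberships to the uniform fixed point.
#' @param seed integer master seed.
#' @return a `mkftm_config` list.
#' @export
mkftm_config <- function(preprocess = preprocess_config(),
                         local_scheme = "raw_tf",
                         global_scheme = "fp_idf",
                         global_max_scope = "corpus",
                         n_components = 0.95,
                         fuzzifier = 1.1, tolerance = 1e-5,
                         max_iterations = 100L, n_starts = 5L,
                         kernels = NULL, seed = 1L) {
  structure(list(preprocess = preprocess, local_scheme = local_scheme,
                 global_scheme = global_scheme,
                 global_max_scope = global_max_scope,
                 n_components = n_components, fuzzifier = fuzzifier,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 n_starts = as.integer(n_starts),
                 kernels = kernels, seed = as.integer(seed)),
            class = "mkftm_config")
}

#' Fit the multiple-kernel fuzzy topic model
#'
#' Runs the full pipeline: preprocessing (skipped when the corpus is
#' already tokenized), bag-of-words counting, FP-IDF weighting, PCA,
#' multiple-kernel fuzzy c-means with F = K clusters, and the conversion of
#' memberships into probability tables. The converged fuzzy membership of
#' document j in cluster k is identified with P(T_k | D_j); the probability
#' tables are computed from the pre-PCA weighted matrix, which is
#' nonnegative — PCA only shapes the clustering geometry.
#'
#' @param corpus an `mkftm_corpus` (raw or already tokenized).
#' @param K number of topics (>= 2).
#' @param config an [mkftm_config()].
#' @return `mkftm_topic_model` with fields `K`, `P_D` (length n),
#'   `P_T_given_D` (n x K), `P_D_joint_T`, `P_D_given_T` (n x K),
#'   `P_W_given_D` (m x n), `P_W_given_T` (m x K), `vocabulary`, `doc_ids`,
#'   `mkfcm` (the clustering result) and `config`.
#' @export
fit_mkftm <- function(corpus, K, config = mkftm_config()) {
  stopifnot(inherits(corpus, "mkftm_corpus"))
  if (K < 2) stop_mkftm("K must be >= 2", class = "mkftm_config_error")
  if (length(corpus) == 0L) {
    stop_mkftm("empty corpus", class = "mkftm_empty_corpus_error")
  }
  if (!is_preprocessed(corpus)) {
    corpus <- preprocess(corpus, config$preprocess)
  }
  dtm <- build_doc_term_matrix(corpus)
  weighted <- apply_weights(dtm, local_scheme = config$local_scheme,
                            global_scheme = config$global_scheme,
                            global_max_scope = config$global_max_scope)
  # FP-IDF can zero out ubiquitous terms; documents made entirely of such
  # terms would lose all mass, so guard against empty columns here
  if (any(Matrix::colSums(weighted$values) <= 0)) {
    stop_mkftm("weighting removed all mass from some document",
               class = "mkftm_degenerate_input_error")
  }
  reduced <- reduce_documents(weighted, n_components = config$n_components)
  mk <- mkfcm_fit(reduced$scores,
                  mkfcm_config(n_clusters = K, fuzzifier = config$fuzzifier,
                               tolerance = config$tolerance,
                               max_iterations = config$max_iterations,
                               seed = config$seed, n_starts = config$n_starts,
                               kernels = config$kernels))
  P_T_given_D <- mk$membership
  P_D <- document_probabilities(weighted)
  td <- topic_document_distribution(P_T_given_D, P_D)
  P_W_given_D <- word_document_distribution(weighted)
  P_W_given_T <- word_topic_distribution(P_W_given_D, td$P_D_given_T)
  structure(list(K = as.integer(K), P_D = P_D, P_T_given_D = P_T_given_D,
                 P_D_joint_T = td$joint, P_D_given_T = td$P_D_given_T,
                 P_W_given_D = P_W_given_D, P_W_given_T = P_W_given_T,
                 vocabulary = corpus$vocabulary, doc_ids = corpus$doc_ids,
                 mkfcm = mk, config = config),
            class = "mkftm_topic_model")
}

#' @export
print.mkftm_topic_model <- function(x, ...) {
  cat(sprintf("<mkftm_topic_model> %d topics, %d documents, %d terms\n",
              x$K, length(x$doc_ids), length(x$vocabulary)))
  invisible(x)
}

#' Top terms of a topic
#'
#' The `count` terms with the largest P(W | T_k); ties are broken by
#' vocabulary order.
#'
#' @param model an `mkftm_topic_model`.
#' @param topic topic index in 1..K.
#' @param count number of terms (1..m).
#' @return character vector of terms.
#' @export
top_words <- function(model, topic, count = 10L) {
  stopifnot(inherits(model, "mkftm_topic_model"))
  if (topic < 1 || topic > model$K) {
    stop_mkftm("topic index out of range", class = "mkftm_input_error")
  }
  count <- as.integer(count)
  stopifnot(count >= 1L, count <= length(model$vocabulary))
  p <- model$P_W_given_T[, topic]
  ord <- order(-p, seq_along(p))   # vocabulary order breaks ties
  model$vocabulary[ord[seq_len(count)]]
}

#' Save / load a fitted topic model
#'
#' Writes the model as a directory of TSV probability tables plus JSON
#' metadata (K, seed, convergence, kernel weights) and the vocabulary and
#' document-id lists.
#'
#' @param model an `mkftm_topic_model`.
#' @param dir output directory (created if absent).
#' @return `save_topic_model` returns `dir` invisibly; `load_topic_model`
#'   rebuilds the model object (without the full clustering trace's
#'   config closure).
#' @export
save_topic_model <- function(model, dir) {
  stopifnot(inherits(model, "mkftm_topic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    format(x, digits = 17, scientific = TRUE, trim = TRUE),
    file.path(dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  wt(matrix(model$P_D, nrow = 1), "p_d.tsv")
  wt(model$P_T_given_D, "p_t_given_d.tsv")
  wt(model$P_D_given_T, "p_d_given_t.tsv")
  wt(model$P_W_given_D, "p_w_given_d.tsv")
  wt(model$P_W_given_T, "p_w_given_t.tsv")
  writeLines(model$vocabulary, file.path(dir, "vocabulary.txt"))
  writeLines(model$doc_ids, file.path(dir, "doc_ids.txt"))
  meta <- list(K = model$K, seed = model$config$seed,
               n_iter = model$mkfcm$n_iter,
               converged = model$mkfcm$converged,
               kernel_weights = model$mkfcm$kernel_weights,
               local_scheme = model$config$local_scheme,
               global_scheme = model$config$global_scheme)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_topic_model
#' @export
load_topic_model <- function(dir) {
  rd <- function(f) as.matrix(utils::read.table(file.path(dir, f),
                                                sep = "\t"))
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  docs <- readLines(file.path(dir, "doc_ids.txt"))
  P_D <- stats::setNames(as.numeric(rd("p_d.tsv")), docs)
  strip <- function(m, rn, cn) {
    dimnames(m) <- list(rn, cn); m
  }
  P_T_given_D <- strip(rd("p_t_given_d.tsv"), docs, NULL)
  model <- list(K = meta$K, P_D = P_D, P_T_given_D = P_T_given_D,
                P_D_joint_T = P_T_given_D * P_D,
                P_D_given_T = strip(rd("p_d_given_t.tsv"), docs, NULL),
                P_W_given_D = strip(rd("p_w_given_d.tsv"), vocab, docs),
                P_W_given_T = strip(rd("p_w_given_t.tsv"), vocab, NULL),
                vocabulary = vocab, doc_ids = docs,
                mkfcm = list(n_iter = meta$n_iter,
                             converged = meta$converged,
                             kernel_weights = meta$kernel_weights),
                config = list(seed = meta$seed,
                              local_scheme = meta$local_scheme,
                              global_scheme = meta$global_scheme))
  class(model) <- "mkftm_topic_model"
  model
}
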