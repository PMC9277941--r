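#' Principal component analysis of weighted document vectors
#'
#' Projects documents (as rows of the transposed weighted matrix) onto
#' their leading principal components before clustering. Columns (terms)
#' are mean-centered but not variance-scaled: the FP-IDF weights are the
#' quantity of interest and standardizing would undo them. Component signs
#' are fixed deterministically by requiring the largest-magnitude loading
#' of every component to be positive, so repeated runs are bit-identical.
#'
#' @param weighted an `mkftm_weighted` (terms x documents).
#' @param n_components either a variance fraction in (0, 1) — the smallest
#'   number of components whose cumulative explained-variance ratio reaches
#'   it, capped at `min(n - 1, 200)` — or an integer number of components
#'   `<= min(n - 1, m)`. Default 0.95.
#' @return An `mkftm_reduced`: `scores` (documents x r), `components`
#'   (terms x r orthonormal loadings), `mean_vector` (per-term means),
#'   `explained_variance_ratio` (length r).
#' @export
reduce_documents <- function(weighted, n_components = 0.95) {
  stopifnot(inherits(weighted, "mkftm_weighted"))
  X <- t(as.matrix(weighted$values))     # documents x terms
  n <- nrow(X); m <- ncol(X)
  if (n < 2L) {
    stop_mkftm("PCA needs at least 2 documents", class = "mkftm_config_error")
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc)
  ev <- sv$d^2                       # variances up to the common 1/(n-1)
  total <- sum(ev)
  evr_full <- if (total > 0) ev / total else rep(0, length(ev))

  max_r <- min(n - 1L, m)
  if (length(n_components) != 1L || !is.numeric(n_components) ||
      n_components <= 0) {
    stop_mkftm("invalid n_components", class = "mkftm_config_error")
  }
  if (n_components < 1) {
    cap <- min(n - 1L, 200L)
    r <- which(cumsum(evr_full) >= n_components - 1e-12)[1]
    if (is.na(r)) r <- cap
    r <- min(r, cap)
  } else {
    r <- as.integer(n_components)
    if (r > max_r) {
      stop_mkftm("n_components = ", r, " exceeds min(n-1, m) = ", max_r,
                 class = "mkftm_config_error")
    }
  }
  r <- max(r, 1L)

  comps <- sv$v[, seq_len(r), drop = FALSE]
  scores <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sv$d[seq_len(r)], r, r)
  # deterministic sign: largest |loading| of each component is positive
  for (k in seq_len(r)) {
    piv <- which.max(abs(comps[, k]))
    if (comps[piv, k] < 0) {
      comps[, k] <- -comps[, k]
      scores[, k] <- -scores[, k]
    }
  }
  rownames(scores) <- weighted$doc_ids
  rownames(comps) <- weighted$vocabulary
  structure(list(scores = scores, components = comps, mean_vector = mu,
                 explained_variance_ratio = evr_full[seq_len(r)],
                 doc_ids = weighted$doc_ids, vocabulary = weighted$vocabulary),
            class = "mkftm_reduced")
}

#' @export
print.mkftm_reduced <- function(x, ...) {
  cat(sprintf("<mkftm_reduced> %d documents x %d components (%.1f%% variance)\n",
              nrow(x$scores), ncol(x$scores),
              100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Write reduced document scores as TSV
#'
#' @param reduced an `mkftm_reduced`.
#' @param path base path; `.scores.tsv` and `.components.tsv` are appended.
#' @export
write_reduced <- function(reduced, path) {
  sc <- data.frame(doc_id = reduced$doc_ids, reduced$scores,
                   check.names = FALSE)
  utils::write.table(sc, paste0(path, ".scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cp <- data.frame(term = reduced$vocabulary, reduced$components,
                   check.names = FALSE)
  utils::write.table(cp, paste0(path, ".components.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
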