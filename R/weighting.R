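#' Build the bag-of-words document-term matrix
#'
#' Counts term occurrences per document into a sparse terms-by-documents
#' matrix. Rows follow the corpus vocabulary order, columns the document
#' order.
#'
#' @param corpus a preprocessed `mkftm_corpus`.
#' @return An `mkftm_dtm`: list with `counts` (sparse dgCMatrix, terms x
#'   documents), `vocabulary`, `doc_ids`, `N` (documents) and `m` (terms).
#' @export
build_doc_term_matrix <- function(corpus) {
  stopifnot(inherits(corpus, "mkftm_corpus"))
  if (!is_preprocessed(corpus) || length(corpus$vocabulary) == 0L) {
    stop_mkftm("corpus has not been preprocessed", class = "mkftm_state_error")
  }
  vocab <- corpus$vocabulary
  n <- length(corpus$doc_ids)
  i <- unlist(lapply(corpus$tokens, function(tk) match(tk, vocab)),
              use.names = FALSE)
  j <- rep.int(seq_len(n), lengths(corpus$tokens))
  counts <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                                 dims = c(length(vocab), n),
                                 dimnames = list(vocab, corpus$doc_ids))
  structure(list(counts = counts, vocabulary = vocab,
                 doc_ids = corpus$doc_ids, N = n, m = length(vocab)),
            class = "mkftm_dtm")
}

#' @export
print.mkftm_dtm <- function(x, ...) {
  cat(sprintf("<mkftm_dtm> %d terms x %d documents, %d nonzeros\n",
              x$m, x$N, Matrix::nnzero(x$counts)))
  invisible(x)
}

#' Cosine-normalize document vectors
#'
#' Divides every document column of the count matrix by its Euclidean norm,
#' the standard vector-space normalization that removes document-length
#' effects. Every output column has unit norm.
#'
#' @param dtm an `mkftm_dtm`.
#' @return An `mkftm_weighted` matrix (local scheme `cosine_normalized`,
#'   global scheme `none`).
#' @export
cosine_normalize_documents <- function(dtm) {
  stopifnot(inherits(dtm, "mkftm_dtm"))
  norms <- sqrt(Matrix::colSums(dtm$counts^2))
  if (any(norms == 0)) {
    stop_mkftm("zero document column", class = "mkftm_degenerate_input_error")
  }
  values <- dtm$counts %*% Matrix::Diagonal(x = 1 / norms)
  dimnames(values) <- dimnames(dtm$counts)
  new_weighted(values, dtm, local_scheme = "cosine_normalized",
               global_scheme = "none")
}

new_weighted <- function(values, dtm, local_scheme, global_scheme) {
  structure(list(values = values, vocabulary = dtm$vocabulary,
                 doc_ids = dtm$doc_ids, N = dtm$N, m = dtm$m,
                 local_scheme = local_scheme, global_scheme = global_scheme),
            class = "mkftm_weighted")
}

#' Corpus-level term statistics
#'
#' Computes, per term, the overall frequency F (total count across the
#' corpus), the document frequency df (number of documents containing the
#' term, i.e. the sum of the presence indicator b(tf) which is 1 where
#' tf > 0), and M, the maximum document frequency over the vocabulary.
#'
#' @param dtm an `mkftm_dtm`.
#' @return `mkftm_global_stats`: list with `F_total`, `df`, `M`, `N`.
#' @export
global_frequency <- function(dtm) {
  stopifnot(inherits(dtm, "mkftm_dtm"))
  F_total <- Matrix::rowSums(dtm$counts)
  df <- Matrix::rowSums(dtm$counts > 0)
  structure(list(F_total = F_total, df = df, M = max(df), N = dtm$N),
            class = "mkftm_global_stats")
}

#' Per-term occurrence probabilities across documents
#'
#' Row-normalizes the count matrix: entry (i, j) is the fraction of term
#' i's corpus occurrences that fall in document j. Each row sums to 1.
#'
#' @param dtm an `mkftm_dtm`.
#' @return sparse matrix, same shape as the counts, row sums 1.
#' @export
term_probability <- function(dtm) {
  stopifnot(inherits(dtm, "mkftm_dtm"))
  rs <- Matrix::rowSums(dtm$counts)
  if (any(rs == 0)) {
    stop_mkftm("zero term row", class = "mkftm_degenerate_input_error")
  }
  P <- Matrix::Diagonal(x = 1 / rs) %*% dtm$counts
  dimnames(P) <- dimnames(dtm$counts)
  P
}

#' Inverse-document-frequency global weights
#'
#' Three global term-weight variants on the corpus statistics, all natural
#' log by default:
#' \describe{
#'   \item{`hybrid_idf`}{`log(M * N / df)`, where M is the maximum document
#'     frequency over the vocabulary and N the number of documents.}
#'   \item{`probabilistic_idf`}{`log((N - df) / df)`; negative for terms in
#'     more than half the documents.}
#'   \item{`fp_idf`}{the fusion weight `log(M * N * (N - df) / df^2)`,
#'     equal to the sum of the other two wherever both are defined.}
#' }
#' Terms present in every document make `N - df = 0`; the zero is smoothed
#' with epsilon = 1/(2N) inside the logarithm so the weight stays finite
#' (and strongly negative, so such terms are zeroed by the nonnegativity
#' floor in [apply_weights()]).
#'
#' @param stats an `mkftm_global_stats` from [global_frequency()].
#' @param base logarithm base (default natural log).
#' @return numeric vector of per-term weights.
#' @name idf_weights
NULL

#' @rdname idf_weights
#' @export
hybrid_idf <- function(stats, base = exp(1)) {
  stopifnot(inherits(stats, "mkftm_global_stats"))
  log(stats$M * stats$N / stats$df, base = base)
}

#' @rdname idf_weights
#' @export
probabilistic_idf <- function(stats, base = exp(1)) {
  stopifnot(inherits(stats, "mkftm_global_stats"))
  eps <- 1 / (2 * stats$N)
  log(pmax(stats$N - stats$df, eps) / stats$df, base = base)
}

#' @rdname idf_weights
#' @export
fp_idf <- function(stats, base = exp(1)) {
  stopifnot(inherits(stats, "mkftm_global_stats"))
  eps <- 1 / (2 * stats$N)
  log(stats$M * stats$N * pmax(stats$N - stats$df, eps) / stats$df^2,
      base = base)
}

#' Apply local and global term weights
#'
#' Builds the weighted ("global term weight", GTW) matrix: each entry is
#' the local weight (raw term frequency or cosine-normalized frequency)
#' multiplied by the chosen per-term global weight. Global weights are
#' floored at zero before multiplication so the result is nonnegative, as
#' the downstream probability tables require; a ubiquitous term (negative
#' weight) therefore contributes nothing.
#'
#' @param dtm an `mkftm_dtm`.
#' @param local_scheme `"raw_tf"` (default) or `"cosine_normalized"`.
#' @param global_scheme `"fp_idf"` (default), `"hybrid_idf"`, `"prob_idf"`
#'   or `"none"`.
#' @param global_max_scope `"corpus"` (default): M in the hybrid/fusion
#'   weights is the corpus-wide maximum document frequency, giving one
#'   weight per term. `"document"`: M is taken per document over the terms
#'   it contains, giving a per-term-per-document weight.
#' @param base logarithm base for the global weights.
#' @return An `mkftm_weighted`.
#' @export
apply_weights <- function(dtm,
                          local_scheme = c("raw_tf", "cosine_normalized"),
                          global_scheme = c("fp_idf", "hybrid_idf",
                                            "prob_idf", "none"),
                          global_max_scope = c("corpus", "document"),
                          base = exp(1)) {
  stopifnot(inherits(dtm, "mkftm_dtm"))
  local_scheme <- match.arg(local_scheme)
  global_scheme <- match.arg(global_scheme)
  global_max_scope <- match.arg(global_max_scope)

  local <- if (local_scheme == "raw_tf") {
    dtm$counts
  } else {
    cosine_normalize_documents(dtm)$values
  }

  stats <- global_frequency(dtm)
  if (global_max_scope == "corpus" || global_scheme %in% c("none", "prob_idf")) {
    g <- switch(global_scheme,
                none = rep(1, dtm$m),
                fp_idf = fp_idf(stats, base = base),
                hybrid_idf = hybrid_idf(stats, base = base),
                prob_idf = probabilistic_idf(stats, base = base))
    values <- Matrix::Diagonal(x = pmax(g, 0)) %*% local
  } else {
    # per-document variant: M_d = max df over the terms present in document d
    values <- as(local, "CsparseMatrix")
    eps <- 1 / (2 * stats$N)
    for (j in seq_len(dtm$N)) {
      rows <- which(dtm$counts[, j] > 0)
      M_d <- max(stats$df[rows])
      dfj <- stats$df[rows]
      g <- switch(global_scheme,
                  fp_idf = log(M_d * stats$N * pmax(stats$N - dfj, eps) / dfj^2,
                               base = base),
                  hybrid_idf = log(M_d * stats$N / dfj, base = base))
      values[rows, j] <- values[rows, j] * pmax(g, 0)
    }
  }
  values <- Matrix::drop0(values)
  dimnames(values) <- dimnames(dtm$counts)
  new_weighted(values, dtm, local_scheme, global_scheme)
}

#' @export
print.mkftm_weighted <- function(x, ...) {
  cat(sprintf("<mkftm_weighted> %d terms x %d documents (local=%s, global=%s)\n",
              x$m, x$N, x$local_scheme, x$global_scheme))
  invisible(x)
}

#' Export / import sparse matrices as MatrixMarket triplet text
#'
#' Writes the sparse matrix in MatrixMarket coordinate format with sidecar
#' `.vocab` and `.docs` files (one entry per line) carrying row and column
#' names.
#'
#' @param x an `mkftm_dtm` or `mkftm_weighted`.
#' @param path base path; `.mtx`, `.vocab` and `.docs` are appended.
#' @return `write_matrix` returns `path` invisibly; `read_dtm` rebuilds an
#'   `mkftm_dtm`.
#' @export
write_matrix <- function(x, path) {
  mat <- if (inherits(x, "mkftm_dtm")) x$counts else x$values
  Matrix::writeMM(as(as(mat, "generalMatrix"), "TsparseMatrix"),
                  paste0(path, ".mtx"))
  writeLines(x$vocabulary, paste0(path, ".vocab"))
  writeLines(x$doc_ids, paste0(path, ".docs"))
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_dtm <- function(path) {
  counts <- as(Matrix::readMM(paste0(path, ".mtx")), "CsparseMatrix")
  vocab <- readLines(paste0(path, ".vocab"))
  docs <- readLines(paste0(path, ".docs"))
  dimnames(counts) <- list(vocab, docs)
  structure(list(counts = counts, vocabulary = vocab, doc_ids = docs,
                 N = ncol(counts), m = nrow(counts)),
            class = "mkftm_dtm")
}
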