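#' Load a plain-text corpus
#'
#' Reads a corpus either from a one-document-per-line text file or from a
#' directory of `.txt` files (one document per file, ordered by filename).
#' The returned corpus has raw text only; call [preprocess()] to tokenize.
#'
#' @param source path to a file (`format = "lines"`) or directory
#'   (`format = "directory"`).
#' @param format `"lines"` or `"directory"`.
#' @return An object of class `mkftm_corpus` with fields `doc_ids`,
#'   `raw_text`, `tokens` (empty lists until preprocessing) and
#'   `vocabulary` (empty until preprocessing).
#' @seealso [preprocess()], [write_corpus()], [read_corpus()]
#' @export
load_corpus <- function(source, format = c("lines", "directory")) {
  format <- match.arg(format)
  if (format == "lines") {
    if (!file.exists(source) || dir.exists(source)) {
      stop_mkftm("corpus source not found: ", source, class = "mkftm_input_error")
    }
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
    if (length(lines) == 0L) {
      stop_mkftm("empty corpus: ", source, class = "mkftm_empty_corpus_error")
    }
    # 0-based line index as the document id
    new_corpus(doc_ids = as.character(seq_along(lines) - 1L), raw_text = lines)
  } else {
    if (!dir.exists(source)) {
      stop_mkftm("corpus directory not found: ", source, class = "mkftm_input_error")
    }
    files <- sort(list.files(source, pattern = "\\.txt$", full.names = TRUE))
    if (length(files) == 0L) {
      stop_mkftm("no .txt files in ", source, class = "mkftm_empty_corpus_error")
    }
    texts <- vapply(files, function(f) {
      paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    }, character(1))
    ids <- sub("\\.txt$", "", basename(files))
    new_corpus(doc_ids = ids, raw_text = unname(texts))
  }
}

new_corpus <- function(doc_ids, raw_text, tokens = NULL, vocabulary = character(0)) {
  stopifnot(length(doc_ids) == length(raw_text), !anyDuplicated(doc_ids))
  structure(
    list(
      doc_ids = as.character(doc_ids),
      raw_text = as.character(raw_text),
      tokens = tokens %||% rep(list(character(0)), length(doc_ids)),
      vocabulary = vocabulary
    ),
    class = "mkftm_corpus"
  )
}

#' @export
print.mkftm_corpus <- function(x, ...) {
  cat(sprintf("<mkftm_corpus> %d documents, vocabulary %d terms%s\n",
              length(x$doc_ids), length(x$vocabulary),
              if (length(x$vocabulary)) "" else " (not preprocessed)"))
  invisible(x)
}

#' @export
length.mkftm_corpus <- function(x) length(x$doc_ids)

is_preprocessed <- function(corpus) {
  length(corpus$vocabulary) > 0L || all(lengths(corpus$tokens) > 0L)
}

#' Preprocessing configuration
#'
#' Controls the text-cleaning chain applied by [preprocess()]: punctuation
#' stripping, lowercasing, whitespace tokenization, minimum token length,
#' stopword removal and Porter stemming, applied in that fixed order.
#'
#' @param lowercase lowercase the text before tokenizing.
#' @param strip_punctuation remove punctuation and symbol characters.
#' @param min_token_length drop tokens shorter than this (default 3).
#' @param stopwords `"english"` for the bundled list, a character vector of
#'   words, a path to a one-word-per-line file, or `NULL` to disable.
#' @param stem apply the Porter stemmer.
#' @return A `mkftm_preprocess_config` list.
#' @export
preprocess_config <- function(lowercase = TRUE, strip_punctuation = TRUE,
                              min_token_length = 3L, stopwords = "english",
                              stem = TRUE) {
  min_token_length <- as.integer(min_token_length)
  stopifnot(min_token_length >= 1L)
  sw <- resolve_stopwords(stopwords)
  structure(
    list(lowercase = isTRUE(lowercase),
         strip_punctuation = isTRUE(strip_punctuation),
         min_token_length = min_token_length,
         stopwords = sw, stem = isTRUE(stem)),
    class = "mkftm_preprocess_config"
  )
}

resolve_stopwords <- function(stopwords) {
  if (is.null(stopwords)) return(character(0))
  if (length(stopwords) == 1L && identical(stopwords, "english")) {
    path <- system.file("extdata", "stopwords_english.txt", package = "mkftm")
    return(readLines(path, encoding = "UTF-8", warn = FALSE))
  }
  if (length(stopwords) == 1L && file.exists(stopwords)) {
    return(readLines(stopwords, encoding = "UTF-8", warn = FALSE))
  }
  as.character(stopwords)
}

#' Preprocess a corpus
#'
#' Applies the cleaning chain in a fixed order: strip punctuation,
#' lowercase, whitespace-tokenize, drop short tokens, drop stopwords,
#' Porter-stem. Documents left with zero tokens are dropped (their ids are
#' reported in a message); keeping them would create zero columns that the
#' downstream per-document normalizations cannot divide by. The vocabulary
#' is rebuilt as the sorted set of surviving tokens.
#'
#' @param corpus an `mkftm_corpus` with raw text.
#' @param config a [preprocess_config()].
#' @return A preprocessed `mkftm_corpus`.
#' @export
preprocess <- function(corpus, config = preprocess_config()) {
  stopifnot(inherits(corpus, "mkftm_corpus"))
  txt <- corpus$raw_text
  if (config$strip_punctuation) {
    # Unicode punctuation plus ASCII symbol characters; digits are kept
    txt <- gsub("[\\p{P}\\p{S}]+", " ", txt, perl = TRUE)
  }
  if (config$lowercase) txt <- tolower(txt)
  toks <- strsplit(trimws(txt), "\\s+", perl = TRUE)
  toks <- lapply(toks, function(tk) {
    tk <- tk[nzchar(tk) & nchar(tk) >= config$min_token_length]
    if (length(config$stopwords)) tk <- tk[!(tk %in% config$stopwords)]
    if (config$stem && length(tk)) tk <- porter_stem(tk)
    tk
  })
  keep <- lengths(toks) > 0L
  if (!all(keep)) {
    message("preprocess: dropped ", sum(!keep), " empty document(s): ",
            paste(corpus$doc_ids[!keep], collapse = ", "))
  }
  vocab <- sort(unique(unlist(toks[keep], use.names = FALSE)))
  new_corpus(doc_ids = corpus$doc_ids[keep],
             raw_text = corpus$raw_text[keep],
             tokens = toks[keep], vocabulary = vocab)
}

# build a corpus directly from token lists (synthetic generator, TSV reload)
corpus_from_tokens <- function(doc_ids, tokens) {
  vocab <- sort(unique(unlist(tokens, use.names = FALSE)))
  new_corpus(doc_ids = doc_ids,
             raw_text = vapply(tokens, paste, character(1), collapse = " "),
             tokens = tokens, vocabulary = vocab)
}

#' Write / read a processed corpus as TSV
#'
#' Serialization for round-tripping: one line per document,
#' `doc_id <TAB> space-joined tokens`. Document order is preserved.
#'
#' @param corpus a preprocessed `mkftm_corpus`.
#' @param path output file.
#' @return `write_corpus` returns `path` invisibly; `read_corpus` returns an
#'   `mkftm_corpus`.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "mkftm_corpus"))
  lines <- paste0(corpus$doc_ids, "\t",
                  vapply(corpus$tokens, paste, character(1), collapse = " "))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) {
    stop_mkftm("empty corpus file: ", path, class = "mkftm_empty_corpus_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1L)
  toks <- lapply(parts, function(p) {
    if (length(p) < 2L) character(0) else strsplit(p[2], " ", fixed = TRUE)[[1]]
  })
  corpus_from_tokens(ids, toks)
}

#' Read a labels file
#'
#' Tab-separated `doc_id <TAB> label`, used for the classification
#' evaluation.
#'
#' @param path TSV file path.
#' @return named character vector of labels, names = doc ids.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("doc_id", "label"))
  stats::setNames(df$label, df$doc_id)
}
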