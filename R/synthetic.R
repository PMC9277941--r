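#' Specification of a synthetic planted-topic corpus
#'
#' Describes a Dirichlet-multinomial corpus generator with known ground
#' truth, used to test every pipeline stage without external data. Each
#' planted topic is a Dirichlet draw over the vocabulary whose
#' concentration (`topic_sharpness`) controls how peaked the topic is
#' (lower = sharper); each document draws a topic mixture from a symmetric
#' Dirichlet (`doc_topic_concentration`; values well below 1 make most
#' documents single-topic dominated), then samples tokens topic-by-topic.
#' Redundancy is modeled as near-duplicate documents: a fraction of
#' documents is duplicated with independent token dropout.
#'
#' @param K_true number of planted topics (>= 2).
#' @param vocab_size vocabulary size m.
#' @param n_docs number of original documents (before duplication).
#' @param doc_length_mean Poisson mean document length (floored at 1).
#' @param topic_sharpness Dirichlet concentration of topic-word
#'   distributions.
#' @param doc_topic_concentration symmetric Dirichlet parameter of
#'   per-document topic mixtures.
#' @param redundancy_rate fraction of documents duplicated (0..1).
#' @param dropout_rate per-token drop probability in duplicates (0..1).
#' @param seed integer seed.
#' @return a `mkftm_synthetic_spec` list.
#' @export
synthetic_spec <- function(K_true = 5L, vocab_size = 500L, n_docs = 200L,
                           doc_length_mean = 60, topic_sharpness = 0.05,
                           doc_topic_concentration = 0.1,
                           redundancy_rate = 0, dropout_rate = 0.1,
                           seed = 1L) {
  stopifnot(K_true >= 2, vocab_size >= K_true, n_docs >= 1,
            doc_length_mean > 0, topic_sharpness > 0,
            doc_topic_concentration > 0,
            redundancy_rate >= 0, redundancy_rate <= 1,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(K_true = as.integer(K_true),
                 vocab_size = as.integer(vocab_size),
                 n_docs = as.integer(n_docs),
                 doc_length_mean = doc_length_mean,
                 topic_sharpness = topic_sharpness,
                 doc_topic_concentration = doc_topic_concentration,
                 redundancy_rate = redundancy_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "mkftm_synthetic_spec")
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1), n, k,
              byrow = TRUE)
  # guard against all-zero rows at very small concentrations
  zero <- rowSums(g) == 0
  if (any(zero)) g[zero, ] <- matrix(stats::runif(sum(zero) * k), ncol = k)
  g / rowSums(g)
}

#' Generate a synthetic corpus with planted topics
#'
#' Fully seeded Dirichlet-multinomial sampling per [synthetic_spec()]. The
#' returned corpus is already tokenized (synthetic tokens `w001`, ...), so
#' preprocessing is bypassed when it is fed to [fit_mkftm()]. Documents
#' that end up empty (possible only at extreme dropout) are re-sampled to
#' length 1.
#'
#' @param spec a [synthetic_spec()].
#' @return `mkftm_synthetic`: list with `corpus` (an `mkftm_corpus`),
#'   `planted_topic_word` (K_true x m, rows sum to 1), `planted_doc_topic`
#'   (rows sum to 1, one per emitted document), `planted_labels` (argmax
#'   topic per document), `duplicate_map` (named list original -> copies).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "mkftm_synthetic_spec"))
  with_seed(spec$seed, {
    m <- spec$vocab_size
    vocab <- sprintf(paste0("w%0", nchar(as.character(m)), "d"), seq_len(m))
    topic_word <- rdirichlet(spec$K_true, rep(spec$topic_sharpness, m))
    doc_topic <- rdirichlet(spec$n_docs,
                            rep(spec$doc_topic_concentration, spec$K_true))
    tokens <- vector("list", spec$n_docs)
    for (j in seq_len(spec$n_docs)) {
      len <- max(1L, stats::rpois(1L, spec$doc_length_mean))
      zs <- sample.int(spec$K_true, len, replace = TRUE, prob = doc_topic[j, ])
      tokens[[j]] <- vapply(zs, function(z) {
        vocab[sample.int(m, 1L, prob = topic_word[z, ])]
      }, character(1))
    }
    doc_ids <- sprintf(paste0("d%0", nchar(as.character(spec$n_docs)), "d"),
                       seq_len(spec$n_docs))

    n_dup <- floor(spec$redundancy_rate * spec$n_docs)
    duplicate_map <- list()
    if (n_dup > 0) {
      originals <- sample.int(spec$n_docs, n_dup)
      for (idx in seq_along(originals)) {
        o <- originals[idx]
        tk <- tokens[[o]]
        keep <- stats::runif(length(tk)) >= spec$dropout_rate
        if (!any(keep)) keep[sample.int(length(tk), 1L)] <- TRUE
        dup_id <- paste0(doc_ids[o], "_dup", idx)
        tokens <- c(tokens, list(tk[keep]))
        doc_ids <- c(doc_ids, dup_id)
        doc_topic <- rbind(doc_topic, doc_topic[o, ])
        duplicate_map[[doc_ids[o]]] <- c(duplicate_map[[doc_ids[o]]], dup_id)
      }
    }
    corpus <- corpus_from_tokens(doc_ids, tokens)
    dimnames(topic_word) <- list(NULL, vocab)
    structure(list(corpus = corpus, planted_topic_word = topic_word,
                   planted_doc_topic = doc_topic,
                   planted_labels = apply(doc_topic, 1L, which.max),
                   duplicate_map = duplicate_map, spec = spec),
              class = "mkftm_synthetic")
  })
}

#' @export
print.mkftm_synthetic <- function(x, ...) {
  cat(sprintf("<mkftm_synthetic> %d documents, %d planted topics, vocab %d\n",
              length(x$corpus$doc_ids), x$spec$K_true, x$spec$vocab_size))
  invisible(x)
}

#' Write a synthetic corpus with its ground-truth sidecar
#'
#' The corpus is written in the same one-document-per-line token format
#' that [read_corpus()] reads back; the planted tables, labels and
#' duplicate map go to a JSON sidecar at `<path>.truth.json`.
#'
#' @param synth an `mkftm_synthetic`.
#' @param path corpus output path.
#' @export
write_synthetic <- function(synth, path) {
  write_corpus(synth$corpus, path)
  truth <- list(planted_topic_word = synth$planted_topic_word,
                planted_doc_topic = synth$planted_doc_topic,
                planted_labels = synth$planted_labels,
                duplicate_map = synth$duplicate_map,
                spec = unclass(synth$spec))
  jsonlite::write_json(truth, paste0(path, ".truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Score recovery of planted structure
#'
#' Greedily matches each recovered topic to an unused planted topic by
#' maximal cosine similarity between word distributions (columns aligned by
#' token name), and compares hard document assignments (argmax of P(T|D))
#' with the planted labels via the adjusted Rand index.
#'
#' @param model an `mkftm_topic_model` fitted on `truth$corpus` with
#'   `K = K_true`.
#' @param truth an `mkftm_synthetic`.
#' @return list: `mean_cosine`, `matched_cosines`, `matching` (recovered ->
#'   planted), `ari`.
#' @export
score_recovery <- function(model, truth) {
  stopifnot(inherits(model, "mkftm_topic_model"),
            inherits(truth, "mkftm_synthetic"))
  if (model$K != truth$spec$K_true) {
    stop_mkftm("model K differs from planted K_true",
               class = "mkftm_config_error")
  }
  planted <- truth$planted_topic_word[, model$vocabulary, drop = FALSE]
  rec <- model$P_W_given_T
  cosine <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  K <- model$K
  sim <- outer(seq_len(K), seq_len(K),
               Vectorize(function(r, p) cosine(rec[, r], planted[p, ])))
  matching <- integer(K)
  used <- logical(K)
  # greedy: repeatedly take the globally best unmatched pair
  for (step in seq_len(K)) {
    masked <- sim
    masked[matching > 0, ] <- -Inf
    masked[, used] <- -Inf
    best <- arrayInd(which.max(masked), dim(masked))
    matching[best[1]] <- best[2]
    used[best[2]] <- TRUE
  }
  matched <- vapply(seq_len(K), function(r) sim[r, matching[r]], numeric(1))
  ari <- mclust::adjustedRandIndex(hard_assignments(model$P_T_given_D),
                                   truth$planted_labels)
  list(mean_cosine = mean(matched), matched_cosines = matched,
       matching = matching, ari = ari)
}
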