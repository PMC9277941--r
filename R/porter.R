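#' Porter stemming algorithm
#'
#' Reduces English words to their stems using the classic Porter (1980)
#' suffix-stripping algorithm: five ordered rule groups driven by the
#' "measure" of a word (the number of vowel-consonant sequences in its
#' consonant/vowel skeleton). Input is assumed lowercase; words shorter
#' than three characters are returned unchanged, as in the reference
#' algorithm.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("patients", "caresses", "relational", "hopping"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem_word, character(1), USE.NAMES = FALSE)
}

# consonant flags for a word: TRUE where the letter acts as a consonant.
# 'y' is a consonant at the start of the word or after a vowel.
.porter_cons_flags <- function(chars) {
  n <- length(chars)
  flags <- logical(n)
  for (i in seq_len(n)) {
    c <- chars[i]
    if (c %in% c("a", "e", "i", "o", "u")) {
      flags[i] <- FALSE
    } else if (c == "y") {
      flags[i] <- if (i == 1L) TRUE else !flags[i - 1L]
    } else {
      flags[i] <- TRUE
    }
  }
  flags
}

# measure m: number of VC sequences in [C](VC)^m[V]
.porter_measure <- function(stem) {
  if (nchar(stem) == 0L) return(0L)
  flags <- .porter_cons_flags(strsplit(stem, "", fixed = TRUE)[[1]])
  # collapse runs, then count vowel-run -> consonant-run transitions
  runs <- rle(flags)$values
  sum(runs[-1] & !runs[-length(runs)])
}

.porter_has_vowel <- function(stem) {
  if (nchar(stem) == 0L) return(FALSE)
  any(!.porter_cons_flags(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.porter_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  flags <- .porter_cons_flags(strsplit(word, "", fixed = TRUE)[[1]])
  flags[n]
}

# *o condition: ends cvc where the final consonant is not w, x or y
.porter_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  flags <- .porter_cons_flags(strsplit(word, "", fixed = TRUE)[[1]])
  last <- substr(word, n, n)
  flags[n - 2L] && !flags[n - 1L] && flags[n] && !(last %in% c("w", "x", "y"))
}

.porter_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n > k && substr(word, n - k + 1L, n) == suffix
}

.porter_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

porter_stem_word <- function(word) {
  if (nchar(word) < 3L) return(word)
  w <- word

  # Step 1a
  if (.porter_ends(w, "sses")) {
    w <- .porter_chop(w, 2L)
  } else if (.porter_ends(w, "ies")) {
    w <- paste0(.porter_chop(w, 3L), "i")
  } else if (!.porter_ends(w, "ss") && .porter_ends(w, "s")) {
    w <- .porter_chop(w, 1L)
  }

  # Step 1b
  fired <- FALSE
  if (.porter_ends(w, "eed")) {
    if (.porter_measure(.porter_chop(w, 3L)) > 0L) w <- .porter_chop(w, 1L)
  } else if (.porter_ends(w, "ed") && .porter_has_vowel(.porter_chop(w, 2L))) {
    w <- .porter_chop(w, 2L); fired <- TRUE
  } else if (.porter_ends(w, "ing") && .porter_has_vowel(.porter_chop(w, 3L))) {
    w <- .porter_chop(w, 3L); fired <- TRUE
  }
  if (fired) {
    if (.porter_ends(w, "at") || .porter_ends(w, "bl") || .porter_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.porter_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .porter_chop(w, 1L)
    } else if (.porter_measure(w) == 1L && .porter_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (.porter_ends(w, "y") && .porter_has_vowel(.porter_chop(w, 1L))) {
    w <- paste0(.porter_chop(w, 1L), "i")
  }

  # Step 2 (condition m > 0 on the stem); longest match decided by suffix table
  step2 <- list(
    c("ational", "ate"), c("tional", "tion"), c("enci", "ence"),
    c("anci", "ance"), c("izer", "ize"), c("abli", "able"), c("alli", "al"),
    c("entli", "ent"), c("eli", "e"), c("ousli", "ous"), c("ization", "ize"),
    c("ation", "ate"), c("ator", "ate"), c("alism", "al"), c("iveness", "ive"),
    c("fulness", "ful"), c("ousness", "ous"), c("aliti", "al"),
    c("iviti", "ive"), c("biliti", "ble")
  )
  w <- .porter_map_suffix(w, step2, min_measure = 1L)

  # Step 3
  step3 <- list(
    c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
    c("ical", "ic"), c("ful", ""), c("ness", "")
  )
  w <- .porter_map_suffix(w, step3, min_measure = 1L)

  # Step 4 (condition m > 1; "ion" additionally needs the stem to end s or t)
  step4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
             "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
             "ous", "ive", "ize")
  # longest suffix first
  step4 <- step4[order(-nchar(step4))]
  for (suf in step4) {
    if (.porter_ends(w, suf)) {
      stem <- .porter_chop(w, nchar(suf))
      ok <- .porter_measure(stem) > 1L
      if (suf == "ion") {
        last <- substr(stem, nchar(stem), nchar(stem))
        ok <- ok && last %in% c("s", "t")
      }
      if (ok) w <- stem
      break
    }
  }

  # Step 5a
  if (.porter_ends(w, "e")) {
    stem <- .porter_chop(w, 1L)
    m <- .porter_measure(stem)
    if (m > 1L || (m == 1L && !.porter_cvc(stem))) w <- stem
  }
  # Step 5b
  if (.porter_measure(w) > 1L && .porter_double_cons(w) &&
      .porter_ends(w, "l")) {
    w <- .porter_chop(w, 1L)
  }
  w
}

# apply the first (longest) matching suffix rule whose stem measure passes
.porter_map_suffix <- function(w, rules, min_measure) {
  sufs <- vapply(rules, `[`, character(1), 1L)
  ord <- order(-nchar(sufs))
  for (idx in ord) {
    suf <- rules[[idx]][1]
    if (.porter_ends(w, suf)) {
      stem <- .porter_chop(w, nchar(suf))
      if (.porter_measure(stem) >= min_measure) {
        w <- paste0(stem, rules[[idx]][2])
      }
      return(w)
    }
  }
  w
}
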