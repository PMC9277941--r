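
# internal: evaluate `expr` under a fixed RNG seed, restoring the caller's
# RNG state afterwards so library code never disturbs user-level randomness
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_mkftm <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mkftm_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
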