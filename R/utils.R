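# Internal helpers: seeded evaluation and sub-seed derivation.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's
# RNG state afterwards so seeded package functions do not perturb the
# user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

# Deterministic sub-seed stream: a Lehmer step keyed by (seed, index),
# kept below 2^31 so the result is a valid R integer seed.
derive_seed <- function(seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) + 1
  x <- (s * 48271 + as.numeric(index) * 16807) %% m
  # one more multiplicative step to decorrelate adjacent indices
  as.integer((x * 48271) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(TRUE)
}
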