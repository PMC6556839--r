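# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards, so library code never perturbs the
# user's RNG stream.
with_rng_seed <- function(seed, expr) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed for stage `k` of a run seeded with `seed`; kept
# strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 279470273 + k * 4294967) %% 2147483647)
}

# z-score a numeric vector with the n-1 (sample) standard deviation.
zscore_vec <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
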