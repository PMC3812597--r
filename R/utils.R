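# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. With seed = NULL the current stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Child seeds below 2^31, derived deterministically from a parent seed.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive number", name)
}

# Half-up rounding: the display convention of the calibration reports
# (7.45 -> 7.5, 9.125 -> 9 at digits = 0).
roundHalfUp <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

# Truncation toward zero at `digits` decimals (display of distances).
truncDecimal <- function(x, digits = 2) {
  s <- 10^digits
  trunc(x * s) / s
}
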