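#' Entropy configuration
#'
#' Community-standard multiscale-entropy parameters: embedding dimension
#' `m = 2` (per channel for multivariate), tolerance `rFraction = 0.15`
#' of the scale-1 SD, embedding lag 1, and scales 1..10 so the coarsest
#' version of a 3,000-sample recording keeps 300 points.
#'
#' @param m embedding dimension (>= 1).
#' @param rFraction tolerance as a fraction of SD, in (0, 1).
#' @param maxScale largest coarse-graining factor (>= 1).
#' @param delay embedding lag (>= 1).
#' @return classed list `EntropyConfig`.
#' @export
entropyConfig <- function(m = 2, rFraction = 0.15, maxScale = 10, delay = 1) {
  if (m < 1 || maxScale < 1 || delay < 1) stopf("counts must be >= 1")
  if (rFraction <= 0 || rFraction >= 1) stopf("'rFraction' must be in (0, 1)")
  structure(list(m = as.integer(m), rFraction = rFraction,
                 maxScale = as.integer(maxScale), delay = as.integer(delay)),
            class = "EntropyConfig")
}

.checkConfigLength <- function(n, config) {
  if (n %/% config$maxScale < 10 * (config$m + 1))
    stopf("series too short: coarse length at max scale (%d) below 10*(m+1)",
          n %/% config$maxScale)
}

#' Coarse-grain a series at scale factor tau
#'
#' Non-overlapping window averaging:
#' \deqn{y_j = \tau^{-1} \sum_{i=(j-1)\tau+1}^{j\tau} x_i, \quad
#'       1 \le j \le \lfloor N/\tau \rfloor.}
#' Scale 1 returns the original series; a trailing partial window is
#' dropped (floor rule).
#'
#' @param x numeric vector.
#' @param tau scale factor (1 <= tau <= length(x)).
#' @return numeric vector of length `floor(length(x) / tau)`.
#' @examples
#' coarseGrain(c(1, 2, 3, 4), 2)  # 1.5 3.5
#' @export
coarseGrain <- function(x, tau) {
  n <- length(x)
  if (tau < 1 || tau != round(tau)) stopf("'tau' must be a positive integer")
  if (tau > n) stopf("invalid scale: tau (%d) exceeds series length (%d)", tau, n)
  if (tau == 1) return(as.numeric(x))
  nb <- n %/% tau
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Sample entropy
#'
#' The negative log conditional probability that two sequences of `m`
#' consecutive points similar within tolerance `r` (Chebyshev distance,
#' self-matches excluded) remain similar when one more point is included:
#' `-log(A/B)` with `B` the matching template pairs at length `m` and `A`
#' at length `m + 1`. A constant series has all templates matching
#' (A = B) and entropy 0. When no template pair matches at either length
#' the value is undefined and `NA` is returned with attribute
#' `undefined = TRUE` (never infinity).
#'
#' @param x numeric vector, length > m + 1.
#' @param m embedding dimension.
#' @param r absolute tolerance (same units as `x`); computed upstream as
#'   `rFraction * sd(x)` by the curve functions.
#' @param delay embedding lag (default 1).
#' @return non-negative scalar, or flagged `NA`.
#' @export
sampleEntropy <- function(x, m = 2, r, delay = 1) {
  x <- as.numeric(x)
  if (length(x) <= m * delay + 1) stopf("series too short for m = %d", m)
  if (stats::sd(x) == 0) return(0)
  if (r <= 0) stopf("'r' must be positive")
  ab <- .sampen_counts(x, as.integer(m), as.integer(delay), r)
  if (ab[1] == 0 || ab[2] == 0)
    return(structure(NA_real_, undefined = TRUE))
  -log(ab[1] / ab[2])
}

#' Multivariate sample entropy
#'
#' Extends sample entropy to p jointly sampled channels via composite
#' delay vectors: each template stacks `m` lagged samples from every
#' channel (dimension `p * m`); the match frequency `B` is the fraction of
#' template pairs within `r`. For the extended frequency `A` the embedding
#' is extended by one sample in each channel in turn and all
#' `p * (N - m*delay)` extended vectors are pooled; `A` is the fraction of
#' matching pairs in that pooled set (each set normalised by its own pair
#' count, so both are conditional-probability estimates). Returns
#' `-log(A/B)`. The construction is symmetric in channel order.
#'
#' @param channels samples x channels numeric matrix (>= 2 columns) or a
#'   list of equal-length vectors.
#' @param m per-channel embedding dimension.
#' @param r absolute tolerance in the (possibly normalised) signal space.
#' @param delay embedding lag.
#' @return the entropy estimate (can be slightly negative at coarse
#'   scales, where the pooled extended-match frequency may exceed the
#'   template-match frequency), or flagged `NA` when no pairs match.
#' @export
multivariateSampleEntropy <- function(channels, m = 2, r, delay = 1) {
  X <- if (is.list(channels)) do.call(cbind, channels) else as.matrix(channels)
  if (ncol(X) < 2L) stopf("need >= 2 channels")
  if (nrow(X) <= m * delay + 1) stopf("series too short for m = %d", m)
  if (all(apply(X, 2, stats::sd) == 0)) return(0)
  if (r <= 0) stopf("'r' must be positive")
  ab <- .mvsampen_counts(X, as.integer(m), as.integer(delay), r)
  if (ab[1] == 0 || ab[2] == 0)
    return(structure(NA_real_, undefined = TRUE))
  nt <- nrow(X) - m * delay
  p <- ncol(X)
  aFrac <- ab[1] / (p * nt * (p * nt - 1) / 2)
  bFrac <- ab[2] / (nt * (nt - 1) / 2)
  -log(aFrac / bFrac)
}

#' Multiscale entropy curve
#'
#' Sample entropy of the coarse-grained series at every scale factor
#' 1..`maxScale`. The tolerance, `rFraction` times the SD, is fixed from the
#' original (scale-1) series and reused at all scales, so the curve
#' reflects structure, not the variance reduction of averaging. Undefined
#' scales (no template matches in a short coarse series) are `NA`.
#'
#' @param x numeric vector.
#' @param config an [entropyConfig()].
#' @return an [EntropyCurve-class].
#' @examples
#' curve <- mseCurve(rnorm(1000), entropyConfig(maxScale = 5))
#' complexityIndex(curve)
#' @export
mseCurve <- function(x, config = entropyConfig()) {
  x <- as.numeric(x)
  .checkConfigLength(length(x), config)
  s <- stats::sd(x)
  if (s == 0) return(.EntropyCurve(rep(0, config$maxScale)))
  r <- config$rFraction * s
  vals <- vapply(seq_len(config$maxScale), function(tau)
    as.numeric(sampleEntropy(coarseGrain(x, tau), config$m, r, config$delay)),
    numeric(1))
  .EntropyCurve(vals)
}

#' Multivariate multiscale entropy curve
#'
#' Channels are normalised to zero mean and unit variance, coarse-grained
#' channel-wise at every scale, and summarised by
#' [multivariateSampleEntropy()] with tolerance `rFraction` in the normalised
#' space (fixed across scales).
#'
#' @param channels samples x channels matrix or list of equal-length
#'   vectors.
#' @param config an [entropyConfig()].
#' @return an [EntropyCurve-class].
#' @export
mmseCurve <- function(channels, config = entropyConfig()) {
  X <- if (is.list(channels)) do.call(cbind, channels) else as.matrix(channels)
  .checkConfigLength(nrow(X), config)
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) return(.EntropyCurve(rep(0, config$maxScale)))
  if (any(sds == 0)) stopf("a channel has zero variance")
  Z <- scale(X)
  r <- config$rFraction
  vals <- vapply(seq_len(config$maxScale), function(tau) {
    C <- apply(Z, 2, coarseGrain, tau = tau)
    as.numeric(multivariateSampleEntropy(C, config$m, r, config$delay))
  }, numeric(1))
  .EntropyCurve(vals)
}
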