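#' Sifting configuration
#'
#' Controls the iterative sifting that extracts intrinsic mode functions
#' (IMFs). One sifting pass subtracts the mean of the upper and lower
#' cubic-spline envelopes from the candidate. Sifting of one IMF stops
#' when the Cauchy-type criterion
#' \eqn{\sum_t m(t)^2 / \sum_t h(t)^2 < } `stopThreshold`
#' (with `m` the mean envelope and `h` the candidate) is met together with
#' the extrema/zero-crossing count condition, or after `maxSiftsPerImf`
#' passes. The decomposition ends when the residue is monotone
#' (extrema-poor) or `maxImfs` is reached. Envelope splines anchor on
#' mirror-extended extrema at both ends to suppress boundary swings.
#'
#' @param maxSiftsPerImf sifting passes cap per IMF (default 50).
#' @param stopThreshold Cauchy criterion threshold (default 0.2).
#' @param maxImfs maximum number of IMFs (default 12).
#' @return classed list `SiftConfig`.
#' @export
siftConfig <- function(maxSiftsPerImf = 50, stopThreshold = 0.2, maxImfs = 12) {
  if (maxSiftsPerImf < 1 || maxImfs < 1) stopf("counts must be >= 1")
  if (stopThreshold <= 0) stopf("'stopThreshold' must be positive")
  structure(list(maxSiftsPerImf = as.integer(maxSiftsPerImf),
                 stopThreshold = stopThreshold,
                 maxImfs = as.integer(maxImfs)),
            class = "SiftConfig")
}

#' Upper, lower, and mean envelopes of a signal
#'
#' Natural cubic splines through the local maxima (upper) and minima
#' (lower), with the mean envelope their average. A signal with fewer
#' than two maxima or two minima cannot be enveloped and is classified a
#' residue (`ok = FALSE`) -- that is the normal termination of a
#' decomposition, not an error.
#'
#' @param signal numeric vector.
#' @return list with `ok`, and when `ok`: `upper`, `lower`, `mean`
#'   (numeric vectors), plus extrema counts `n_max`, `n_min`.
#' @export
envelopes <- function(signal) {
  if (anyNA(signal) || any(!is.finite(signal))) stopf("signal must be finite")
  .envelopes_cpp(as.numeric(signal))
}

#' Test the two IMF conditions
#'
#' An intrinsic mode function must (1) have extrema and zero-crossing
#' counts differing by at most one, and (2) have a mean envelope that
#' tends to zero everywhere. Condition (2) is checked as
#' \eqn{\sum m(t)^2 / \sum x(t)^2 \le} `stopThreshold`. Zero crossings are
#' strict sign changes; a run of exact zeros counts once.
#'
#' @param candidate numeric vector.
#' @param stopThreshold tolerance for the mean-envelope criterion.
#' @return logical.
#' @examples
#' t <- seq(0, 10, by = 0.02)
#' isIMF(sin(2 * pi * t))        # TRUE
#' isIMF(sin(2 * pi * t) + 10)   # FALSE
#' @export
isIMF <- function(candidate, stopThreshold = 0.2) {
  x <- as.numeric(candidate)
  ne <- .count_extrema(x)
  nz <- .count_zero_crossings(x)
  if (abs(ne - nz) > 1L) return(FALSE)
  env <- .envelopes_cpp(x)
  if (!env$ok) return(FALSE)
  sx <- sum(x^2)
  if (sx == 0) return(FALSE)
  sum(env$mean^2) / sx <= stopThreshold
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions by iterative sifting,
#' fastest oscillation first, until the residue is monotone. The
#' decomposition is strictly additive: the IMFs plus the residue
#' reconstruct the input to numerical precision.
#'
#' @param signal finite numeric vector, length >= 8.
#' @param config a [siftConfig()].
#' @param fs sampling rate (Hz), carried for downstream frequency analysis.
#' @return an [IMFDecomposition-class].
#' @examples
#' t <- seq(0, 10, by = 0.02)
#' dec <- emd(sin(2 * pi * 0.5 * t) + sin(2 * pi * 8 * t), fs = 50)
#' nIMF(dec)
#' @export
emd <- function(signal, config = siftConfig(), fs = 1) {
  x <- as.numeric(signal)
  if (anyNA(x) || any(!is.finite(x))) stopf("signal contains NaN/Inf")
  if (length(x) < 8L) stopf("signal too short (length >= 8 required)")
  res <- .emd_cpp(x, config$stopThreshold, config$maxSiftsPerImf, config$maxImfs)
  new("IMFDecomposition", imfs = res$imfs, residue = res$residue,
      fs = as.numeric(fs))
}
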