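#' Dominant frequency of an IMF
#'
#' Frequency of the maximum-magnitude FFT bin (DC excluded), refined by a
#' power-weighted mean over the peak bin and its two neighbours. A
#' spectrally flat signal is flagged broadband (attribute
#' `broadband = TRUE`): the peak region (peak bin and its two neighbours)
#' must concentrate at least 5% of the total spectral power, otherwise no
#' single oscillation dominates and the value should not be read as a
#' characteristic frequency. An all-zero signal has no defined frequency
#' and returns `NA` with attribute `undefined = TRUE`.
#'
#' @param imf numeric vector, length >= 16.
#' @param fs sampling rate (Hz).
#' @return dominant frequency in Hz (scalar), with attributes `broadband`
#'   and (when all-zero) `undefined`.
#' @examples
#' t <- seq(0, 60, by = 0.02)
#' dominantFrequency(sin(2 * pi * 1 * t), fs = 50)  # ~1.00
#' @export
dominantFrequency <- function(imf, fs) {
  x <- as.numeric(imf)
  n <- length(x)
  if (n < 16L) stopf("IMF too short for frequency estimation (need >= 16)")
  if (all(x == 0))
    return(structure(NA_real_, undefined = TRUE, broadband = FALSE))
  pw <- Mod(stats::fft(x))^2
  half <- pw[2:(n %/% 2 + 1)]            # positive frequencies, DC excluded
  freqs <- (seq_along(half)) * fs / n
  k <- which.max(half)
  idx <- max(1L, k - 1L):min(length(half), k + 1L)
  f <- sum(freqs[idx] * half[idx]) / sum(half[idx])
  broadband <- sum(half[idx]) < 0.05 * sum(half)
  structure(f, broadband = broadband)
}

#' Dominant-frequency table of a decomposition
#'
#' Applies [dominantFrequency()] to every IMF. For a multivariate set the
#' reported frequency is the mean across channels (the channel-aligned
#' IMFs share a band by construction).
#'
#' @param decomposition an [IMFDecomposition-class] or
#'   [MultivariateIMFSet-class].
#' @param fs sampling rate (Hz); defaults to the decomposition's.
#' @return data.frame: `imf`, `dominant_hz`, `broadband`.
#' @export
imfFrequencyTable <- function(decomposition, fs = samplingRate(decomposition)) {
  mats <- if (is(decomposition, "MultivariateIMFSet"))
    decomposition@imfs else list(imfMatrix(decomposition))
  q <- ncol(mats[[1L]])
  if (q == 0L)
    return(data.frame(imf = integer(), dominant_hz = numeric(),
                      broadband = logical()))
  rows <- lapply(seq_len(q), function(j) {
    fv <- lapply(mats, function(m) dominantFrequency(m[, j], fs))
    vals <- vapply(fv, as.numeric, numeric(1))
    data.frame(imf = j, dominant_hz = mean(vals, na.rm = TRUE),
               broadband = all(vapply(fv, attr, logical(1), "broadband")))
  })
  do.call(rbind, rows)
}

#' Select the sub-cutoff sway band from a decomposition
#'
#' Physiological COP sway lies below 2 Hz, so the sway signal is
#' reconstructed as the sum of the IMFs whose dominant frequency falls
#' below the cutoff. Selection is frequency-driven rather than by fixed
#' IMF ordinals: which ordinals land below 2 Hz depends on the sampling
#' rate and signal content (for 50 Hz quiet-stance recordings the
#' selected pair is typically IMFs 5 and 6). The residue, a trend rather
#' than an oscillation, is never selected.
#'
#' @param decomposition an [IMFDecomposition-class] or
#'   [MultivariateIMFSet-class].
#' @param fs sampling rate (Hz); defaults to the decomposition's.
#' @param cutoff cutoff frequency in Hz (default 2).
#' @return a [BandSelection-class]; `reconstructedSignal()` gives the
#'   samples x channels band-limited sway.
#' @export
selectBand <- function(decomposition, fs = samplingRate(decomposition),
                       cutoff = 2.0) {
  tab <- imfFrequencyTable(decomposition, fs)
  if (nrow(tab) == 0L) stopf("decomposition has no IMFs")
  sel <- which(!is.na(tab$dominant_hz) & tab$dominant_hz < cutoff)
  if (length(sel) == 0L)
    stopf(paste("no IMF below the %g Hz cutoff; inspect the frequency table",
                "(imfFrequencyTable) -- the sway band may be absent"), cutoff)
  mats <- if (is(decomposition, "MultivariateIMFSet"))
    decomposition@imfs else list(imfMatrix(decomposition))
  rec <- vapply(mats, function(m) rowSums(m[, sel, drop = FALSE]),
                numeric(nrow(mats[[1L]])))
  colnames(rec) <- if (is(decomposition, "MultivariateIMFSet"))
    channelNames(decomposition) else "signal"
  new("BandSelection", cutoff = cutoff, selectedIndices = as.integer(sel),
      frequencies = tab, reconstructed = rec, fs = as.numeric(fs))
}
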