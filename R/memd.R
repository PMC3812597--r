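#' Direction vectors for multivariate envelope projection
#'
#' Multivariate EMD estimates the local mean of a p-channel signal by
#' projecting it along K directions on the unit hypersphere of the channel
#' space and averaging the directional envelopes. The direction set is a
#' low-discrepancy Hammersley point set mapped to unit vectors, so it is
#' deterministic given `(nChannels, K)`: for two channels the K angles are
#' spaced uniformly on \[0, 2pi); for three or more channels the
#' Hammersley hypercube points are pushed through the Gaussian quantile
#' map and normalised. The `seed` argument is accepted for interface
#' symmetry with the stochastic generators and ignored.
#'
#' @param nChannels channel-space dimension (>= 2).
#' @param K number of directions (>= 4; at least twice `nChannels`).
#' @param seed ignored (the construction is deterministic).
#' @return K x nChannels numeric matrix of unit row vectors.
#' @export
directionSet <- function(nChannels, K = 64, seed = NULL) {
  if (K < 4) stopf("'K' must be >= 4")
  if (nChannels < 2) stopf("'nChannels' must be >= 2")
  if (K < 2 * nChannels) stopf("'K' must be at least twice 'nChannels'")
  if (nChannels == 2L) {
    th <- 2 * pi * (seq_len(K) - 1) / K
    return(cbind(cos(th), sin(th)))
  }
  # radical-inverse (van der Corput) sequence in a prime base
  radInv <- function(i, base) {
    f <- 1 / base
    r <- 0
    while (i > 0) {
      r <- r + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    r
  }
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37)
  U <- matrix(0, K, nChannels)
  U[, 1] <- (seq_len(K) - 0.5) / K
  for (d in 2:nChannels)
    U[, d] <- vapply(seq_len(K), radInv, numeric(1), base = primes[d - 1])
  U[U <= 0] <- 0.5 / K
  G <- stats::qnorm(U)
  G / sqrt(rowSums(G^2))
}

#' Multivariate mean envelope
#'
#' For each direction: project the signal onto the direction, locate the
#' projection's local maxima, interpolate every channel through its values
#' at those times with a natural cubic spline (mirror-extended at the
#' ends), and average the directional envelopes over the usable directions
#' (those whose projection has at least two maxima). When fewer than half
#' the directions are usable the signal is classified a residue.
#'
#' @param s samples x channels numeric matrix.
#' @param dirs direction matrix from [directionSet()].
#' @return list with `ok` (FALSE = residue classification), `mean`
#'   (samples x channels matrix), and `usable` (direction count).
#' @export
multivariateMeanEnvelope <- function(s, dirs) {
  s <- as.matrix(s)
  if (ncol(dirs) != ncol(s)) stopf("direction dimension != channel count")
  .mv_envelope_cpp(s, dirs)
}

#' Multivariate empirical mode decomposition
#'
#' Joint sifting of all channels against the multivariate mean envelope,
#' so every channel receives the same number of IMFs and corresponding IMF
#' indices occupy a common frequency band across channels. Sifting of one
#' multivariate IMF stops when the Cauchy criterion on the norm of the
#' mean envelope, \eqn{\sum_t \|m(t)\|^2 / \sum_t \|h(t)\|^2 <}
#' `stopThreshold`, is met, or at the sift cap.
#'
#' @param s samples x channels numeric matrix (>= 2 channels), or a
#'   [COPSeries-class] (its ML and AP channels).
#' @param config a [siftConfig()].
#' @param K number of projection directions.
#' @param fs sampling rate (Hz).
#' @param channelNames optional channel names.
#' @return a [MultivariateIMFSet-class].
#' @export
memd <- function(s, config = siftConfig(), K = 64, fs = 1,
                 channelNames = NULL) {
  if (is(s, "COPSeries")) {
    fs <- samplingRate(s)
    s <- cbind(ML = copX(s), AP = copY(s))
  }
  s <- as.matrix(s)
  if (ncol(s) < 2L) stopf("need >= 2 channels")
  if (anyNA(s) || any(!is.finite(s))) stopf("signal contains NaN/Inf")
  if (is.null(channelNames))
    channelNames <- if (!is.null(colnames(s))) colnames(s)
                    else paste0("ch", seq_len(ncol(s)))
  dirs <- directionSet(ncol(s), K)
  res <- .memd_cpp(s, dirs, config$stopThreshold, config$maxSiftsPerImf,
                   config$maxImfs)
  imfs <- res$imfs
  names(imfs) <- channelNames
  colnames(res$residue) <- channelNames
  new("MultivariateIMFSet", imfs = imfs, residues = res$residue,
      channelNames = channelNames, fs = as.numeric(fs))
}

#' Noise-assisted multivariate EMD of a two-channel sway signal
#'
#' Adds independent white Gaussian noise channels alongside the ML and AP
#' sway channels, runs [memd()] on the composite, and returns only the two
#' signal channels' IMFs. The noise channels occupy the dyadic filter bank
#' of the decomposition and anchor the IMF-to-frequency-band alignment,
#' which suppresses mode mixing (intermittent fast activity leaking into a
#' slow IMF and vice versa). Noise SD is `noiseSdFraction` times the mean
#' SD of the signal channels.
#'
#' @param xMl,xAp equal-length numeric vectors, or pass a
#'   [COPSeries-class] as `xMl`.
#' @param nNoiseChannels number of white-noise channels (>= 1, default 1).
#' @param noiseSdFraction noise SD as a fraction of the mean signal-channel
#'   SD (must be > 0; default 0.1).
#' @param seed integer seed for the noise channels.
#' @param config a [siftConfig()].
#' @param K number of projection directions.
#' @param fs sampling rate (Hz); taken from the `COPSeries` when given.
#' @return a [MultivariateIMFSet-class] with channels `ML`, `AP` (noise
#'   channels dropped).
#' @export
naMemd <- function(xMl, xAp = NULL, nNoiseChannels = 1, noiseSdFraction = 0.1,
                   seed = 1, config = siftConfig(), K = 64, fs = 1) {
  if (is(xMl, "COPSeries")) {
    fs <- samplingRate(xMl)
    xAp <- copY(xMl)
    xMl <- copX(xMl)
  }
  if (length(xMl) != length(xAp)) stopf("ML and AP must have equal length")
  if (nNoiseChannels < 1) stopf("'nNoiseChannels' must be >= 1")
  if (noiseSdFraction <= 0)
    stopf("'noiseSdFraction' must be positive (degenerate noise forbidden)")
  n <- length(xMl)
  sdn <- noiseSdFraction * mean(c(stats::sd(xMl), stats::sd(xAp)))
  if (sdn <= 0) stopf("signal channels have zero variance")
  noise <- withSeed(seed, matrix(stats::rnorm(n * nNoiseChannels, 0, sdn), n))
  s <- cbind(xMl, xAp, noise)
  colnames(s) <- c("ML", "AP", paste0("noise", seq_len(nNoiseChannels)))
  dec <- memd(s, config = config, K = K, fs = fs)
  keep <- 1:2
  new("MultivariateIMFSet", imfs = dec@imfs[keep],
      residues = dec@residues[, keep, drop = FALSE],
      channelNames = c("ML", "AP"), fs = dec@fs)
}
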