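#' @import methods
NULL

#' Two-channel center-of-pressure trajectory
#'
#' `COPSeries` holds a sampled center-of-pressure (COP) trajectory: the
#' medial-lateral (ML, `x`) and anterior-posterior (AP, `y`) displacement of
#' the resultant ground-reaction force, in centimetres, at a fixed sampling
#' rate. The COP trace over time (the stabilogram) is the raw material of
#' postural-sway analysis.
#'
#' @slot fs sampling rate in Hz.
#' @slot x ML displacement per sample (cm).
#' @slot y AP displacement per sample (cm).
#'
#' @exportClass COPSeries
setClass("COPSeries",
  representation(fs = "numeric", x = "numeric", y = "numeric"))

setValidity("COPSeries", function(object) {
  msg <- character()
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@x) != length(object@y))
    msg <- c(msg, "'x' and 'y' must have equal length")
  if (anyNA(object@x) || anyNA(object@y) ||
      any(!is.finite(object@x)) || any(!is.finite(object@y)))
    msg <- c(msg, "COP channels must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a COPSeries
#'
#' @param x,y equal-length numeric vectors: ML and AP displacement (cm).
#' @param fs sampling rate (Hz).
#' @return A [COPSeries-class] object.
#' @examples
#' cop <- COPSeries(x = sin(seq(0, 2 * pi, length.out = 100)),
#'                  y = cos(seq(0, 2 * pi, length.out = 100)), fs = 50)
#' @export
COPSeries <- function(x, y, fs) {
  new("COPSeries", fs = as.numeric(fs), x = as.numeric(x), y = as.numeric(y))
}

#' Four-channel force-plate recording
#'
#' Vertical reaction forces from the four corner load cells of a square
#' force platform, plus the geometry constant `L` (cm) that maps force
#' imbalance to COP displacement. With total load
#' \eqn{W = F_1 + F_2 + F_3 + F_4}, the COP is
#' \eqn{X = [(F_4 + F_2) - (F_1 + F_3)] L / W},
#' \eqn{Y = [(F_3 + F_4) - (F_1 + F_2)] L / W}.
#'
#' @slot fs sampling rate in Hz.
#' @slot f1,f2,f3,f4 per-sample vertical reaction force of each corner load
#'   cell (same unit for all four; Newtons in the shipped generators).
#' @slot L geometry constant (cm), positive.
#'
#' @exportClass ForcePlateSeries
setClass("ForcePlateSeries",
  representation(fs = "numeric", f1 = "numeric", f2 = "numeric",
                 f3 = "numeric", f4 = "numeric", L = "numeric"))

setValidity("ForcePlateSeries", function(object) {
  msg <- character()
  n <- length(object@f1)
  if (length(object@f2) != n || length(object@f3) != n || length(object@f4) != n)
    msg <- c(msg, "all four force channels must have equal length")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@L) != 1L || !is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "'L' must be a single positive number")
  fmat <- cbind(object@f1, object@f2, object@f3, object@f4)
  if (anyNA(fmat) || any(!is.finite(fmat)))
    msg <- c(msg, "forces must be finite")
  else if (any(fmat < -1e-9))
    msg <- c(msg, "forces must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ForcePlateSeries
#'
#' @param f1,f2,f3,f4 equal-length numeric force channels (one per corner
#'   load cell, non-negative).
#' @param fs sampling rate (Hz).
#' @param L plate geometry constant (cm).
#' @return A [ForcePlateSeries-class] object.
#' @export
ForcePlateSeries <- function(f1, f2, f3, f4, fs, L) {
  new("ForcePlateSeries", fs = as.numeric(fs), f1 = as.numeric(f1),
      f2 = as.numeric(f2), f3 = as.numeric(f3), f4 = as.numeric(f4),
      L = as.numeric(L))
}

#' Empirical mode decomposition of a single channel
#'
#' Ordered intrinsic mode functions (IMFs, fastest first) and the final
#' residue from sifting one signal. The decomposition is additive: the
#' column sum of `imfs` plus `residue` reconstructs the input.
#'
#' @slot imfs numeric matrix, one column per IMF (may have zero columns).
#' @slot residue numeric vector, the monotone (or extrema-poor) remainder.
#' @slot fs sampling rate in Hz.
#'
#' @exportClass IMFDecomposition
setClass("IMFDecomposition",
  representation(imfs = "matrix", residue = "numeric", fs = "numeric"))

setValidity("IMFDecomposition", function(object) {
  msg <- character()
  if (nrow(object@imfs) != length(object@residue) && ncol(object@imfs) > 0)
    msg <- c(msg, "IMFs and residue must have the same number of samples")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Channel-aligned multivariate IMF decomposition
#'
#' The result of multivariate EMD: every channel carries the same number of
#' IMFs and corresponding IMF indices occupy a common frequency band across
#' channels (the alignment property that motivates MEMD over running EMD
#' per channel).
#'
#' @slot imfs list of numeric matrices (samples x IMFs), one per channel;
#'   identical dimensions across channels.
#' @slot residues numeric matrix, samples x channels.
#' @slot channelNames character vector naming the channels.
#' @slot fs sampling rate in Hz.
#'
#' @exportClass MultivariateIMFSet
setClass("MultivariateIMFSet",
  representation(imfs = "list", residues = "matrix",
                 channelNames = "character", fs = "numeric"))

setValidity("MultivariateIMFSet", function(object) {
  msg <- character()
  p <- length(object@imfs)
  if (p < 2L) msg <- c(msg, "need at least two channels")
  if (length(object@channelNames) != p)
    msg <- c(msg, "'channelNames' must name every channel")
  if (p >= 1L) {
    dims <- vapply(object@imfs, dim, integer(2))
    if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
      msg <- c(msg, "all channels must share identical IMF matrix dimensions")
    if (ncol(object@residues) != p || nrow(object@residues) != dims[1L, 1L])
      msg <- c(msg, "'residues' must be samples x channels")
  }
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Entropy-versus-scale curve with its complexity index
#'
#' Sample entropy (univariate or multivariate) evaluated on coarse-grained
#' versions of a signal, one value per scale factor. The complexity index
#' (CI) is the area under this curve: the plain sum of the per-scale
#' entropies. Scales whose entropy is undefined (no template matches in a
#' short coarse series) hold `NA`; the stored CI sums the defined values
#' and is flagged partial.
#'
#' @slot scales integer scale factors 1..tau_max.
#' @slot values entropy per scale; `NA` marks an undefined scale.
#' @slot ci sum of the defined per-scale entropies.
#' @slot nDefined number of scales with a defined entropy value.
#'
#' @exportClass EntropyCurve
setClass("EntropyCurve",
  representation(scales = "integer", values = "numeric", ci = "numeric",
                 nDefined = "integer"))

setValidity("EntropyCurve", function(object) {
  msg <- character()
  if (length(object@scales) != length(object@values))
    msg <- c(msg, "'scales' and 'values' must have equal length")
  if (length(object@scales) < 1L)
    msg <- c(msg, "curve must have at least one scale")
  ok <- !is.na(object@values)
  if (!isTRUE(all.equal(object@ci, sum(object@values[ok]))))
    msg <- c(msg, "'ci' must equal the sum of the defined entropy values")
  if (object@nDefined != sum(ok))
    msg <- c(msg, "'nDefined' inconsistent with 'values'")
  if (length(msg)) msg else TRUE
})

.EntropyCurve <- function(values, scales = seq_along(values)) {
  ok <- !is.na(values)
  new("EntropyCurve", scales = as.integer(scales), values = as.numeric(values),
      ci = sum(values[ok]), nDefined = sum(ok))
}

#' Sub-band selection from an IMF decomposition
#'
#' Records which IMFs fell below the frequency cutoff, the per-IMF dominant
#' frequencies that drove the choice, and the band-limited reconstruction
#' (the sum of the selected IMFs, per channel).
#'
#' @slot cutoff cutoff frequency in Hz.
#' @slot selectedIndices integer IMF indices below the cutoff.
#' @slot frequencies data.frame: `imf`, `dominant_hz`, `broadband`.
#' @slot reconstructed numeric matrix, samples x channels (one column for a
#'   univariate decomposition).
#' @slot fs sampling rate in Hz.
#'
#' @exportClass BandSelection
setClass("BandSelection",
  representation(cutoff = "numeric", selectedIndices = "integer",
                 frequencies = "data.frame", reconstructed = "matrix",
                 fs = "numeric"))

#' Synthetic sway cohort
#'
#' A per-subject, per-condition collection of [COPSeries-class] recordings
#' generated by [genCohort()]. Conditions follow the four-condition balance
#' protocol: eyes open (EO), eyes closed (EC), and both repeated on a
#' compliant water pad (WPEO, WPEC).
#'
#' @slot series list of length `nSubjects`; each element a named list of
#'   `COPSeries`, one per condition.
#' @slot conditions character vector of condition names.
#' @slot seed integer seed the cohort was generated from.
#'
#' @exportClass SwayCohort
setClass("SwayCohort",
  representation(series = "list", conditions = "character", seed = "integer"))

setValidity("SwayCohort", function(object) {
  msg <- character()
  if (length(object@series) < 1L) msg <- c(msg, "cohort must have >= 1 subject")
  ok <- vapply(object@series, function(s)
    all(object@conditions %in% names(s)), logical(1))
  if (!all(ok))
    msg <- c(msg, sprintf("subjects missing conditions: %s",
                          paste(which(!ok), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Static calibration report for a force platform
#'
#' Per-point means and error ratios from repeated static point-load tests,
#' with the per-axis summary statistics (mean error ratio and maximum error
#' distance) used to judge static accuracy.
#'
#' @slot table per-point data.frame: verification coordinates, measured
#'   mean and SD per axis, error ratios (percent) for X, Y and
#'   origin distance, plus verification/measured origin distances.
#' @slot meanRatio named numeric, raw mean error ratios in percent
#'   (`x`, `y`, `distance`).
#' @slot meanRatioDisplay same, rounded for display (one decimal for the
#'   axes, nearest integer for distance).
#' @slot maxErrorDistance named numeric (cm): farthest verification
#'   coordinate on each axis times the displayed mean error ratio.
#' @slot absoluteErrorFlag logical; `TRUE` when a zero verification
#'   coordinate forced an absolute (cm) rather than relative error entry.
#'
#' @exportClass StaticReport
setClass("StaticReport",
  representation(table = "data.frame", meanRatio = "numeric",
                 meanRatioDisplay = "numeric", maxErrorDistance = "numeric",
                 absoluteErrorFlag = "logical"))

#' Reliability (ICC) report
#'
#' Intraclass correlation coefficient, two-way random effects, absolute
#' agreement, single measure (ICC(2,1)), with the conventional
#' classification: above 0.75 "excellent", 0.4 to 0.75 "fair to good",
#' below 0.4 "poor".
#'
#' @slot icc the coefficient.
#' @slot classification one of "excellent", "fair to good", "poor".
#' @slot meanSquares named numeric: rows (repeats), columns (targets),
#'   error mean squares from the two-way ANOVA decomposition.
#'
#' @exportClass ReliabilityReport
setClass("ReliabilityReport",
  representation(icc = "numeric", classification = "character",
                 meanSquares = "numeric"))

#' Cohort comparison report
#'
#' Per-subject complexity indices and the paired condition comparisons
#' (EO vs WPEO, EC vs WPEC): improvement rate (percentage of subjects whose
#' CI dropped in the perturbed condition) and a paired significance test,
#' reported per sway direction (ML, AP) for per-channel multiscale entropy
#' and jointly (ML&AP) for multivariate multiscale entropy.
#'
#' @slot ci data.frame: `subject`, `condition`, `direction`, `ci`.
#' @slot comparisons data.frame: `pair`, `direction`, `entropy`,
#'   `improvement_raw`, `improvement_display`, `p_value`.
#' @slot config list of the pipeline configuration used.
#'
#' @exportClass CohortReport
setClass("CohortReport",
  representation(ci = "data.frame", comparisons = "data.frame",
                 config = "list"))
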