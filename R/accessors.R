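#' @describeIn COPSeries sampling rate (Hz).
#' @param x a `COPSeries`.
#' @export
setMethod("samplingRate", "COPSeries", function(x) x@fs)

#' @describeIn ForcePlateSeries sampling rate (Hz).
#' @param x a `ForcePlateSeries`.
#' @export
setMethod("samplingRate", "ForcePlateSeries", function(x) x@fs)

#' @export
setMethod("samplingRate", "IMFDecomposition", function(x) x@fs)

#' @export
setMethod("samplingRate", "MultivariateIMFSet", function(x) x@fs)

#' @export
setMethod("nSamples", "COPSeries", function(x) length(x@x))

#' @export
setMethod("nSamples", "ForcePlateSeries", function(x) length(x@f1))

#' @export
setMethod("nSamples", "IMFDecomposition", function(x) length(x@residue))

#' @export
setMethod("nSamples", "MultivariateIMFSet", function(x) nrow(x@residues))

#' @export
setMethod("copX", "COPSeries", function(x) x@x)

#' @export
setMethod("copY", "COPSeries", function(x) x@y)

#' @export
setMethod("forceMatrix", "ForcePlateSeries", function(x)
  cbind(f1 = x@f1, f2 = x@f2, f3 = x@f3, f4 = x@f4))

#' @export
setMethod("plateGeometry", "ForcePlateSeries", function(x) x@L)

#' @export
setMethod("imfMatrix", "IMFDecomposition", function(x, channel) x@imfs)

#' @export
setMethod("imfMatrix", "MultivariateIMFSet", function(x, channel) {
  if (is.character(channel)) channel <- match(channel, x@channelNames)
  x@imfs[[channel]]
})

#' @export
setMethod("imfResidue", "IMFDecomposition", function(x, channel) x@residue)

#' @export
setMethod("imfResidue", "MultivariateIMFSet", function(x, channel) {
  if (is.character(channel)) channel <- match(channel, x@channelNames)
  x@residues[, channel]
})

#' @export
setMethod("nIMF", "IMFDecomposition", function(x) ncol(x@imfs))

#' @export
setMethod("nIMF", "MultivariateIMFSet", function(x) ncol(x@imfs[[1L]]))

#' @export
setMethod("channelNames", "MultivariateIMFSet", function(x) x@channelNames)

#' @export
setMethod("entropyValues", "EntropyCurve", function(x) x@values)

#' @export
setMethod("entropyScales", "EntropyCurve", function(x) x@scales)

#' @export
setMethod("complexityIndex", "EntropyCurve", function(x) {
  if (x@nDefined == length(x@values)) return(x@ci)
  structure(x@ci, partial = TRUE, nDefined = x@nDefined)
})

#' @export
setMethod("selectedIndices", "BandSelection", function(x) x@selectedIndices)

#' @export
setMethod("reconstructedSignal", "BandSelection", function(x) x@reconstructed)

#' @export
setMethod("nSubjects", "SwayCohort", function(x) length(x@series))

#' @export
setMethod("conditionNames", "SwayCohort", function(x) x@conditions)

#' @export
setMethod("subjectSeries", "SwayCohort", function(x, i) x@series[[i]])

#' Coerce a COPSeries to a data.frame
#'
#' Columns `time_s`, `x_cm`, `y_cm` (the CSV dialect used throughout the
#' package).
#' @param x a [COPSeries-class].
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "COPSeries", function(x, ...) {
  n <- length(x@x)
  data.frame(time_s = (seq_len(n) - 1) / x@fs, x_cm = x@x, y_cm = x@y)
})

#' @export
setMethod("as.data.frame", "ForcePlateSeries", function(x, ...) {
  n <- length(x@f1)
  data.frame(time_s = (seq_len(n) - 1) / x@fs,
             f1 = x@f1, f2 = x@f2, f3 = x@f3, f4 = x@f4)
})

setMethod("show", "COPSeries", function(object) {
  cat(sprintf("COPSeries: %d samples at %g Hz (%.1f s)\n",
              length(object@x), object@fs, length(object@x) / object@fs))
  cat(sprintf("  ML (x): mean %.3f cm, SD %.3f cm\n",
              mean(object@x), stats::sd(object@x)))
  cat(sprintf("  AP (y): mean %.3f cm, SD %.3f cm\n",
              mean(object@y), stats::sd(object@y)))
})

setMethod("show", "ForcePlateSeries", function(object) {
  cat(sprintf("ForcePlateSeries: %d samples at %g Hz, L = %g cm\n",
              length(object@f1), object@fs, object@L))
  w <- object@f1 + object@f2 + object@f3 + object@f4
  cat(sprintf("  total load W: mean %.2f, range [%.2f, %.2f]\n",
              mean(w), min(w), max(w)))
})

setMethod("show", "IMFDecomposition", function(object) {
  cat(sprintf("IMFDecomposition: %d IMFs + residue, %d samples at %g Hz\n",
              ncol(object@imfs), length(object@residue), object@fs))
})

setMethod("show", "MultivariateIMFSet", function(object) {
  cat(sprintf("MultivariateIMFSet: %d channels (%s), %d aligned IMFs, %d samples at %g Hz\n",
              length(object@imfs), paste(object@channelNames, collapse = ", "),
              ncol(object@imfs[[1L]]), nrow(object@residues), object@fs))
})

setMethod("show", "EntropyCurve", function(object) {
  cat(sprintf("EntropyCurve over %d scales; CI = %.4f", length(object@scales), object@ci))
  if (object@nDefined < length(object@scales))
    cat(sprintf(" (partial: %d defined scales)", object@nDefined))
  cat("\n")
  print(stats::setNames(round(object@values, 4), paste0("tau=", object@scales)))
})

setMethod("show", "BandSelection", function(object) {
  cat(sprintf("BandSelection: cutoff %g Hz; selected IMFs: %s\n",
              object@cutoff, paste(object@selectedIndices, collapse = ", ")))
  print(object@frequencies, row.names = FALSE)
})

setMethod("show", "SwayCohort", function(object) {
  cat(sprintf("SwayCohort: %d subjects x %d conditions (%s), seed %d\n",
              length(object@series), length(object@conditions),
              paste(object@conditions, collapse = ", "), object@seed))
})

setMethod("show", "StaticReport", function(object) {
  cat("Static calibration report\n")
  print(object@table, row.names = FALSE)
  cat(sprintf("Mean error ratio: X %.1f%%, Y %.1f%%, distance %d%%\n",
              object@meanRatioDisplay[["x"]], object@meanRatioDisplay[["y"]],
              as.integer(object@meanRatioDisplay[["distance"]])))
  cat(sprintf("Max error distance: X %.2f cm, Y %.2f cm, distance %.2f cm\n",
              object@maxErrorDistance[["x"]], object@maxErrorDistance[["y"]],
              object@maxErrorDistance[["distance"]]))
})

setMethod("show", "ReliabilityReport", function(object) {
  cat(sprintf("ICC(2,1) = %.3f: %s reliability\n", object@icc, object@classification))
})

setMethod("show", "CohortReport", function(object) {
  cat(sprintf("CohortReport: %d subjects, decomposition = %s\n",
              length(unique(object@ci$subject)), object@config$decomposition))
  print(object@comparisons, row.names = FALSE)
})

#' ICC value accessor
#' @param x a [ReliabilityReport-class].
#' @return the intraclass correlation coefficient.
#' @export
iccValue <- function(x) x@icc

#' ICC classification accessor
#' @param x a [ReliabilityReport-class].
#' @return "excellent", "fair to good", or "poor".
#' @export
iccClassification <- function(x) x@classification

#' Per-subject complexity indices of a cohort report
#' @param x a [CohortReport-class].
#' @return data.frame with `subject`, `condition`, `direction`, `ci`.
#' @export
cohortCI <- function(x) x@ci

#' Condition-pair comparisons of a cohort report
#' @param x a [CohortReport-class].
#' @return data.frame with improvement rates and p-values.
#' @export
cohortComparisons <- function(x) x@comparisons
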