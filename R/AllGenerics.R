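#' Sampling rate accessor
#' @param x an object with a sampling rate.
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Number of samples accessor
#' @param x a time-series object.
#' @return integer sample count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' ML (X) channel accessor
#' @param x a [COPSeries-class].
#' @return numeric vector (cm).
#' @export
setGeneric("copX", function(x) standardGeneric("copX"))

#' AP (Y) channel accessor
#' @param x a [COPSeries-class].
#' @return numeric vector (cm).
#' @export
setGeneric("copY", function(x) standardGeneric("copY"))

#' Force channels as a matrix
#' @param x a [ForcePlateSeries-class].
#' @return samples x 4 numeric matrix, columns `f1`..`f4`.
#' @export
setGeneric("forceMatrix", function(x) standardGeneric("forceMatrix"))

#' Plate geometry constant accessor
#' @param x a [ForcePlateSeries-class].
#' @return the geometry constant L (cm).
#' @export
setGeneric("plateGeometry", function(x) standardGeneric("plateGeometry"))

#' IMF matrix accessor
#' @param x a decomposition object.
#' @param channel for multivariate sets, the channel index or name.
#' @return numeric matrix, samples x IMFs.
#' @export
setGeneric("imfMatrix", function(x, channel) standardGeneric("imfMatrix"))

#' Residue accessor
#' @param x a decomposition object.
#' @param channel for multivariate sets, the channel index or name.
#' @return numeric vector.
#' @export
setGeneric("imfResidue", function(x, channel) standardGeneric("imfResidue"))

#' Number of IMFs
#' @param x a decomposition object.
#' @return integer IMF count (common across channels for multivariate sets).
#' @export
setGeneric("nIMF", function(x) standardGeneric("nIMF"))

#' Channel names accessor
#' @param x a multivariate object.
#' @return character vector.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Entropy values per scale
#' @param x an [EntropyCurve-class].
#' @return numeric vector, `NA` where undefined.
#' @export
setGeneric("entropyValues", function(x) standardGeneric("entropyValues"))

#' Scale factors of an entropy curve
#' @param x an [EntropyCurve-class].
#' @return integer vector.
#' @export
setGeneric("entropyScales", function(x) standardGeneric("entropyScales"))

#' Complexity index (area under the entropy curve)
#'
#' The complexity index (CI) summarises an entropy-versus-scale curve as
#' the plain sum of the per-scale entropy values. Lower CI indicates a more
#' regular, less complex signal; in balance analysis, perturbed stance
#' (e.g., standing on a compliant pad) lowers the CI of the sway signal.
#'
#' @param x an [EntropyCurve-class].
#' @return the CI. When some scales are undefined the sum covers the
#'   defined scales only and carries attributes `partial = TRUE` and
#'   `nDefined`.
#' @examples
#' complexityIndex(.EntropyCurve(c(1, 1, 1, 1)))  # 4
#' @export
setGeneric("complexityIndex", function(x) standardGeneric("complexityIndex"))

#' Selected IMF indices of a band selection
#' @param x a [BandSelection-class].
#' @return integer vector.
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' Band-limited reconstruction accessor
#' @param x a [BandSelection-class].
#' @return samples x channels numeric matrix.
#' @export
setGeneric("reconstructedSignal", function(x) standardGeneric("reconstructedSignal"))

#' Number of subjects in a cohort
#' @param x a [SwayCohort-class].
#' @return integer.
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' Condition names of a cohort
#' @param x a [SwayCohort-class].
#' @return character vector.
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))

#' Extract one subject's recordings
#' @param x a [SwayCohort-class].
#' @param i subject index.
#' @return named list of [COPSeries-class], one per condition.
#' @export
setGeneric("subjectSeries", function(x, i) standardGeneric("subjectSeries"))
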