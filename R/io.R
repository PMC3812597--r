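#' Read and write COP trajectories as CSV
#'
#' The CSV dialect is plain UTF-8 with a mandatory header and '.' decimal
#' separator: columns `time_s`, `x_cm`, `y_cm`. The sampling rate is
#' recovered from the time column on read.
#'
#' @param path file path.
#' @return `readCOPSeries()`: a [COPSeries-class].
#' @export
readCOPSeries <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "x_cm", "y_cm")
  if (!all(need %in% names(d)))
    stopf("COP CSV must have columns %s", paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(d$time_s))
  COPSeries(x = d$x_cm, y = d$y_cm, fs = fs)
}

#' @rdname readCOPSeries
#' @param cop a [COPSeries-class].
#' @export
writeCOPSeries <- function(cop, path) {
  utils::write.csv(as.data.frame(cop), path, row.names = FALSE)
  invisible(path)
}

#' Read and write force-plate recordings as CSV
#'
#' Columns `time_s`, `f1`, `f2`, `f3`, `f4` (forces in N); header
#' mandatory.
#'
#' @param path file path.
#' @param L plate geometry constant (cm), not stored in the CSV.
#' @return `readForcePlateSeries()`: a [ForcePlateSeries-class].
#' @export
readForcePlateSeries <- function(path, L) {
  d <- utils::read.csv(path)
  need <- c("time_s", "f1", "f2", "f3", "f4")
  if (!all(need %in% names(d)))
    stopf("force CSV must have columns %s", paste(need, collapse = ", "))
  fs <- 1 / stats::median(diff(d$time_s))
  ForcePlateSeries(f1 = d$f1, f2 = d$f2, f3 = d$f3, f4 = d$f4, fs = fs, L = L)
}

#' @rdname readForcePlateSeries
#' @param series a [ForcePlateSeries-class].
#' @export
writeForcePlateSeries <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort condition configuration from YAML
#'
#' The file maps condition names (EO, EC, WPEO, WPEC) to sway-model
#' fields; omitted fields take the [swayModel()] defaults. Example:
#' ```yaml
#' EO:  {amplitudeScale: 0.4, regularity: 0.35}
#' WPEO: {amplitudeScale: 0.72, regularity: 0.65}
#' ```
#'
#' @param path YAML file path.
#' @return named list of [conditionSpec()] objects.
#' @export
readSwayConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (length(cfg) == 0L) stopf("empty condition configuration")
  out <- lapply(names(cfg), function(nm) {
    conditionSpec(nm, do.call(swayModel, cfg[[nm]]))
  })
  names(out) <- names(cfg)
  out
}

#' Load the bundled static calibration table
#'
#' A published static verification of a prototype four-load-cell platform:
#' eight point-load locations, each measured ten times, with per-point
#' measured means, SDs, and percent error ratios for the X axis, Y axis,
#' and origin distance as tabulated by the device report. Used to exercise
#' [staticErrorReport()] on real calibration numbers.
#'
#' @return list with `verification` (data.frame `x`, `y`) and `ratios`
#'   (data.frame as required by [staticErrorReport()]).
#' @export
bundledStaticCalibration <- function() {
  d <- utils::read.csv(system.file("extdata", "static_calibration.csv",
                                   package = "copbalance"))
  list(verification = d[, c("x", "y")],
       ratios = d[, c("mean_x", "mean_y", "sd_x", "sd_y",
                      "ratio_x", "ratio_y", "ratio_d")])
}

#' Load the bundled dynamic-test radius measurements
#'
#' Ten repeated radius measurements of a mechanically generated 10 cm
#' circular displacement, from the same device report as
#' [bundledStaticCalibration()].
#'
#' @return list with `radius` (the true radius, cm) and `measured`
#'   (numeric vector of ten measured radii, cm).
#' @export
bundledDynamicRadii <- function() {
  d <- utils::read.csv(system.file("extdata", "dynamic_radii.csv",
                                   package = "copbalance"))
  list(radius = 10, measured = d$measured_radius_cm)
}
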