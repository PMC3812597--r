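#' COP localization from four load-cell channels
#'
#' Converts the four corner reaction forces of a square force platform to
#' the center-of-pressure trajectory. With total load
#' \eqn{W = F_1 + F_2 + F_3 + F_4} and geometry constant \eqn{L},
#' \deqn{X = [(F_4 + F_2) - (F_1 + F_3)] \cdot L / W}
#' \deqn{Y = [(F_3 + F_4) - (F_1 + F_2)] \cdot L / W}
#' The mapping is scale-invariant in the total load: only the force
#' *imbalance* matters, so a full single-corner load maps to a corner of
#' the \eqn{[-L, L]} square. Whether `L` is the full or half sensor
#' spacing is a property of the device; the formula is applied as given
#' and the geometry convention is the caller's responsibility.
#'
#' @param series a [ForcePlateSeries-class].
#' @return a [COPSeries-class] with the same sampling rate.
#' @examples
#' fp <- ForcePlateSeries(175, 175, 175, 175, fs = 50, L = 11.5)
#' copX(copFromForces(fp))  # 0
#' @export
copFromForces <- function(series) {
  stopifnot(is(series, "ForcePlateSeries"))
  W <- series@f1 + series@f2 + series@f3 + series@f4
  bad <- which(W <= 0)
  if (length(bad))
    stopf("degenerate load: total force W <= 0 at sample(s) %s",
          paste(utils::head(bad, 5L), collapse = ", "))
  L <- series@L
  x <- ((series@f4 + series@f2) - (series@f1 + series@f3)) * L / W
  y <- ((series@f3 + series@f4) - (series@f1 + series@f2)) * L / W
  COPSeries(x = x, y = y, fs = series@fs)
}

#' Distance from the plate origin, report display convention
#'
#' Euclidean norm of a plate coordinate, truncated (not rounded) toward
#' zero at two decimals -- the convention used in static calibration
#' tables, where e.g. \eqn{\sqrt{222.5} = 14.916...} is printed as 14.91.
#' Internal computations elsewhere keep full precision; this function is
#' the display form.
#'
#' @param x,y coordinates in cm (vectorised).
#' @return distance in cm, truncated to two decimals.
#' @examples
#' distanceFromOrigin(11.5, 9.5)  # 14.91
#' distanceFromOrigin(3, 4)       # 5
#' @export
distanceFromOrigin <- function(x, y) {
  truncDecimal(sqrt(x^2 + y^2), 2)
}

#' Static calibration error report
#'
#' Summarises repeated static point-load measurements against their known
#' verification locations. Per point and axis the error ratio is
#' \eqn{|\bar{x}_{meas} - x_{ver}| / |x_{ver}|} (percent); the origin
#' distance gets the analogous ratio. The axis summary is the arithmetic
#' mean of the per-point ratios, and the maximum error distance is the
#' farthest verification coordinate on that axis times the (displayed)
#' mean ratio.
#'
#' Two input forms are accepted. Either `measured` is a long data.frame of
#' repeated raw measurements (`point`, `x`, `y`), from which per-point
#' means, SDs and ratios are computed; or `ratios` supplies a
#' pre-tabulated report (per-point measured means/SDs and percent error
#' ratios), as when re-analysing a published calibration table whose
#' rounded entries are taken as given.
#'
#' A verification coordinate of exactly zero makes the relative error
#' undefined; the absolute error (cm) is reported in its place and the
#' report is flagged (`absoluteErrorFlag`), and such points are excluded
#' from that axis' mean ratio.
#'
#' @param verification data.frame with columns `x`, `y`: the true point
#'   locations (cm).
#' @param measured optional data.frame of repeated measurements with
#'   columns `point` (row index into `verification`), `x`, `y`.
#' @param ratios optional data.frame with columns `mean_x`, `mean_y`,
#'   `sd_x`, `sd_y`, `ratio_x`, `ratio_y`, `ratio_d` (ratios in percent),
#'   one row per verification point.
#' @return a [StaticReport-class].
#' @export
staticErrorReport <- function(verification, measured = NULL, ratios = NULL) {
  stopifnot(is.data.frame(verification), all(c("x", "y") %in% names(verification)))
  np <- nrow(verification)
  if (is.null(measured) == is.null(ratios))
    stopf("supply exactly one of 'measured' or 'ratios'")

  if (!is.null(measured)) {
    stopifnot(all(c("point", "x", "y") %in% names(measured)))
    if (!all(seq_len(np) %in% measured$point))
      stopf("every verification point needs >= 1 repeat")
    agg <- function(v, f) vapply(seq_len(np), function(i)
      f(v[measured$point == i]), numeric(1))
    sd0 <- function(v) if (length(v) > 1L) stats::sd(v) else 0
    mean_x <- agg(measured$x, mean); mean_y <- agg(measured$y, mean)
    sd_x <- agg(measured$x, sd0);    sd_y <- agg(measured$y, sd0)
    relerr <- function(m, v) ifelse(v == 0, abs(m), 100 * abs(m - v) / abs(v))
    ratio_x <- relerr(mean_x, verification$x)
    ratio_y <- relerr(mean_y, verification$y)
    d_ver <- sqrt(verification$x^2 + verification$y^2)
    d_meas <- sqrt(mean_x^2 + mean_y^2)
    ratio_d <- relerr(d_meas, d_ver)
  } else {
    need <- c("mean_x", "mean_y", "sd_x", "sd_y", "ratio_x", "ratio_y", "ratio_d")
    stopifnot(all(need %in% names(ratios)), nrow(ratios) == np)
    mean_x <- ratios$mean_x; mean_y <- ratios$mean_y
    sd_x <- ratios$sd_x;     sd_y <- ratios$sd_y
    ratio_x <- ratios$ratio_x; ratio_y <- ratios$ratio_y; ratio_d <- ratios$ratio_d
    d_ver <- sqrt(verification$x^2 + verification$y^2)
    d_meas <- sqrt(mean_x^2 + mean_y^2)
  }

  zero_x <- verification$x == 0
  zero_y <- verification$y == 0
  zero_d <- d_ver == 0
  flag <- any(zero_x) || any(zero_y) || any(zero_d)

  mr <- c(x = mean(ratio_x[!zero_x]), y = mean(ratio_y[!zero_y]),
          distance = mean(ratio_d[!zero_d]))
  mrd <- c(x = roundHalfUp(mr[["x"]], 1), y = roundHalfUp(mr[["y"]], 1),
           distance = roundHalfUp(mr[["distance"]], 0))
  med <- c(x = max(abs(verification$x)) * mrd[["x"]] / 100,
           y = max(abs(verification$y)) * mrd[["y"]] / 100,
           distance = max(truncDecimal(d_ver, 2)) * mrd[["distance"]] / 100)

  tab <- data.frame(
    ver_x = verification$x, ver_y = verification$y,
    mean_x = mean_x, mean_y = mean_y, sd_x = sd_x, sd_y = sd_y,
    ratio_x = ratio_x, ratio_y = ratio_y,
    dist_ver = truncDecimal(d_ver, 2), dist_meas = d_meas, ratio_d = ratio_d)

  new("StaticReport", table = tab, meanRatio = mr, meanRatioDisplay = mrd,
      maxErrorDistance = med, absoluteErrorFlag = flag)
}

#' Mean error ratios of a static report
#' @param x a [StaticReport-class].
#' @param display return the display-rounded values (default) or the raw
#'   means.
#' @return named numeric (percent): `x`, `y`, `distance`.
#' @export
staticMeanRatios <- function(x, display = TRUE) {
  if (display) x@meanRatioDisplay else x@meanRatio
}

#' Maximum error distances of a static report
#' @param x a [StaticReport-class].
#' @return named numeric (cm): `x`, `y`, `distance`.
#' @export
staticMaxErrorDistances <- function(x) x@maxErrorDistance

#' Per-point table of a static report
#' @param x a [StaticReport-class].
#' @return data.frame.
#' @export
staticTable <- function(x) x@table

#' Dynamic radius statistic of a circular COP trajectory
#'
#' For validating a platform against a mechanically generated circular
#' displacement: each sample's excursion is its distance from the circle
#' center, and the radius statistic is the mean excursion plus the sample
#' standard deviation of the excursions (mean + SD, n-1 denominator). For
#' a noiseless circle this equals the true radius.
#'
#' @param cop a [COPSeries-class].
#' @param center numeric length-2, circle center (cm). Default origin.
#' @return radius statistic in cm.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)
#' dynamicRadiusStat(COPSeries(10 * cos(th), 10 * sin(th), fs = 50))  # 10
#' @export
dynamicRadiusStat <- function(cop, center = c(0, 0)) {
  stopifnot(is(cop, "COPSeries"))
  if (nSamples(cop) < 2L) stopf("need >= 2 samples")
  exc <- sqrt((cop@x - center[1])^2 + (cop@y - center[2])^2)
  mean(exc) + stats::sd(exc)
}
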