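#' Maximum lagged cross-correlation between two signals
#'
#' Pearson correlation of the overlapping segments of `a` and `b` at every
#' integer lag within +/- `maxLagFraction` of the series length, after
#' optionally trimming `startTrim` samples from the front of both (the
#' "aligned to the same start point" convention when comparing two
#' recording devices). Values near 1 mean the two signals agree; values
#' near -1 mean they are anti-phase.
#'
#' @param a,b numeric vectors of equal length (>= 2) sampled at the same
#'   rate.
#' @param maxLagFraction lag search half-width as a fraction of the series
#'   length (default 0.1).
#' @param startTrim samples dropped from the start of both series.
#' @return list: `maximum` (the peak correlation), `lag` (its lag in
#'   samples, positive = `b` delayed), `atZero` (lag-0 correlation).
#' @examples
#' x <- sin(seq(0, 20, by = 0.02))
#' maxCrossCorrelation(x, x)$maximum  # 1
#' @export
maxCrossCorrelation <- function(a, b, maxLagFraction = 0.1, startTrim = 0) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stopf("series must have equal length")
  if (startTrim > 0) {
    a <- a[-seq_len(startTrim)]
    b <- b[-seq_len(startTrim)]
  }
  n <- length(a)
  if (n < 2L) stopf("need >= 2 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("zero-variance input: correlation undefined")
  maxLag <- floor(maxLagFraction * n)
  lags <- -maxLag:maxLag
  cc <- vapply(lags, function(l) {
    if (l >= 0) {
      av <- a[seq_len(n - l)]; bv <- b[seq_len(n - l) + l]
    } else {
      av <- a[seq_len(n + l) - l]; bv <- b[seq_len(n + l)]
    }
    if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
    stats::cor(av, bv)
  }, numeric(1))
  k <- which.max(cc)
  list(maximum = cc[k], lag = lags[k], atZero = cc[lags == 0])
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' ANOVA mean squares of a repeats x targets matrix (repeats as "raters",
#' targets as "subjects"):
#' \deqn{ICC = \frac{MS_T - MS_E}{MS_T + (k-1) MS_E + (k/n)(MS_R - MS_E)}}
#' with \eqn{MS_T} the between-target, \eqn{MS_R} the between-repeat and
#' \eqn{MS_E} the residual mean squares, `k` repeats and `n` targets.
#' Classified "excellent" above 0.75, "fair to good" between 0.4 and
#' 0.75, "poor" below 0.4.
#'
#' @param measurements numeric matrix, repeats (rows) x targets (columns),
#'   at least two of each.
#' @return a [ReliabilityReport-class].
#' @examples
#' m <- rbind(c(1, 5, 9), c(1, 5, 9))  # perfect agreement
#' iccValue(icc(m))  # 1
#' @export
icc <- function(measurements) {
  m <- as.matrix(measurements)
  k <- nrow(m); n <- ncol(m)
  if (k < 2 || n < 2) stopf("need >= 2 repeats and >= 2 targets")
  if (stats::sd(as.numeric(m)) == 0)
    stopf("constant matrix: variance decomposition undefined")
  grand <- mean(m)
  colm <- colMeans(m)   # per target
  rowm <- rowMeans(m)   # per repeat
  ssT <- k * sum((colm - grand)^2)
  ssR <- n * sum((rowm - grand)^2)
  ssE <- sum((m - outer(rowm, colm, "+") + grand)^2)
  msT <- ssT / (n - 1)
  msR <- ssR / (k - 1)
  msE <- ssE / ((n - 1) * (k - 1))
  val <- (msT - msE) / (msT + (k - 1) * msE + k * (msR - msE) / n)
  cls <- if (val > 0.75) "excellent"
         else if (val >= 0.4) "fair to good"
         else "poor"
  new("ReliabilityReport", icc = val, classification = cls,
      meanSquares = c(targets = msT, repeats = msR, error = msE))
}

#' Improvement rate between paired condition CIs
#'
#' The percentage of subjects whose complexity index decreased from
#' condition A to condition B (a CI drop marks the expected response to a
#' balance perturbation). The raw percentage is returned together with a
#' display value rounded to the nearest 5% -- the granularity such rates
#' are conventionally reported at over cohorts of 20.
#'
#' @param ciA,ciB equal-length per-subject CI vectors (paired).
#' @return list: `raw` (percent), `display` (nearest 5%), `n`.
#' @examples
#' improvementRate(c(3, 4, 5), c(2, 5, 4))$raw  # 66.67
#' @export
improvementRate <- function(ciA, ciB) {
  if (length(ciA) != length(ciB)) stopf("pairing error: unequal lengths")
  n <- length(ciA)
  if (n < 1L) stopf("need >= 1 pair")
  raw <- 100 * sum(ciB < ciA) / n
  list(raw = raw, display = 5 * roundHalfUp(raw / 5), n = n)
}

#' Paired significance test between condition CIs
#'
#' Two-sided Wilcoxon signed-rank test on the paired per-subject CI
#' values, exact for n <= 25 (small cohorts, unknown CI distribution). A
#' paired t-test is available via `method = "t"`.
#'
#' @param ciA,ciB equal-length per-subject CI vectors, n >= 5.
#' @param method `"wilcoxon"` (default) or `"t"`.
#' @return the p-value.
#' @export
pairedConditionTest <- function(ciA, ciB, method = c("wilcoxon", "t")) {
  method <- match.arg(method)
  if (length(ciA) != length(ciB)) stopf("pairing error: unequal lengths")
  n <- length(ciA)
  if (n < 5L) stopf("need >= 5 pairs for the paired test")
  d <- ciA - ciB
  if (all(d == 0)) stopf("all differences zero: test degenerate")
  if (method == "t") return(stats::t.test(ciA, ciB, paired = TRUE)$p.value)
  stats::wilcox.test(ciA, ciB, paired = TRUE, exact = n <= 25)$p.value
}

# Band-limited ML/AP reconstruction for one recording under one
# decomposition route.
.reconstructSway <- function(cop, decomposition, config, cutoff,
                             naSeed, naNoiseChannels, naNoiseFraction, K) {
  if (decomposition == "emd") {
    dml <- emd(copX(cop), config = config, fs = samplingRate(cop))
    dap <- emd(copY(cop), config = config, fs = samplingRate(cop))
    ml <- reconstructedSignal(selectBand(dml, cutoff = cutoff))[, 1]
    ap <- reconstructedSignal(selectBand(dap, cutoff = cutoff))[, 1]
    cbind(ML = ml, AP = ap)
  } else {
    dec <- naMemd(cop, nNoiseChannels = naNoiseChannels,
                  noiseSdFraction = naNoiseFraction, seed = naSeed,
                  config = config, K = K)
    reconstructedSignal(selectBand(dec, cutoff = cutoff))
  }
}

#' Run the full cohort balance pipeline
#'
#' For every subject and condition: decompose the two sway channels
#' (univariate EMD per channel, or noise-assisted multivariate EMD
#' jointly), reconstruct the sub-`cutoff` sway band from the selected
#' IMFs, and compute the complexity index -- per direction (ML, AP) from
#' the multiscale entropy curve, and/or jointly (ML&AP) from the
#' multivariate multiscale entropy curve. Conditions are then compared
#' pairwise (EO vs WPEO, EC vs WPEC) by improvement rate and a paired
#' signed-rank test. With fewer than 5 subjects the p-value is `NA`
#' (flagged by the small-n rule of the test).
#'
#' The report is deterministic given the cohort (itself seeded) and
#' `seed`, which drives the noise channels of the noise-assisted route.
#'
#' @param cohort a [SwayCohort-class] whose conditions include the
#'   compared pairs.
#' @param decomposition `"na-memd"` (default) or `"emd"`.
#' @param entropy character vector among `"mse"`, `"mmse"`; both may be
#'   requested and share the one decomposition per recording.
#' @param entropyCfg an [entropyConfig()].
#' @param siftCfg a [siftConfig()].
#' @param cutoff band cutoff in Hz (default 2).
#' @param K projection directions for the multivariate route.
#' @param naNoiseChannels,naNoiseFraction noise-assisted EMD parameters.
#' @param seed seed for the noise channels (one child seed per
#'   subject-condition).
#' @param pairs list of length-2 character vectors naming the compared
#'   condition pairs.
#' @return a [CohortReport-class].
#' @export
runCohortPipeline <- function(cohort, decomposition = c("na-memd", "emd"),
                              entropy = c("mse", "mmse"),
                              entropyCfg = entropyConfig(),
                              siftCfg = siftConfig(), cutoff = 2.0, K = 64,
                              naNoiseChannels = 1, naNoiseFraction = 0.1,
                              seed = 1,
                              pairs = list(c("EO", "WPEO"), c("EC", "WPEC"))) {
  stopifnot(is(cohort, "SwayCohort"))
  decomposition <- match.arg(decomposition)
  entropy <- match.arg(entropy, c("mse", "mmse"), several.ok = TRUE)
  ns <- nSubjects(cohort)
  conds <- unname(conditionNames(cohort))
  for (s in seq_len(ns)) {
    have <- names(subjectSeries(cohort, s))
    if (!all(conds %in% have))
      stopf("incomplete subject %d: missing condition(s) %s", s,
            paste(setdiff(conds, have), collapse = ", "))
  }
  naSeeds <- matrix(childSeeds(seed, ns * length(conds)), nrow = ns)

  rows <- list()
  for (s in seq_len(ns)) {
    for (ci in seq_along(conds)) {
      cop <- subjectSeries(cohort, s)[[conds[ci]]]
      rec <- .reconstructSway(cop, decomposition, siftCfg, cutoff,
                              naSeeds[s, ci], naNoiseChannels,
                              naNoiseFraction, K)
      if ("mse" %in% entropy) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = conds[ci], direction = c("ML", "AP"),
          entropy = "mse",
          ci = c(as.numeric(complexityIndex(mseCurve(rec[, "ML"], entropyCfg))),
                 as.numeric(complexityIndex(mseCurve(rec[, "AP"], entropyCfg)))))
      }
      if ("mmse" %in% entropy) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, condition = conds[ci], direction = "ML&AP",
          entropy = "mmse",
          ci = as.numeric(complexityIndex(mmseCurve(rec, entropyCfg))))
      }
    }
  }
  ciTab <- do.call(rbind, rows)

  cmp <- list()
  for (pr in pairs) {
    for (dir in unique(ciTab$direction)) {
      sub <- ciTab[ciTab$direction == dir, ]
      a <- sub$ci[sub$condition == pr[1]][order(sub$subject[sub$condition == pr[1]])]
      b <- sub$ci[sub$condition == pr[2]][order(sub$subject[sub$condition == pr[2]])]
      if (!length(a)) next
      ir <- improvementRate(a, b)
      pv <- if (ns >= 5 && !all(a == b)) pairedConditionTest(a, b) else NA_real_
      cmp[[length(cmp) + 1L]] <- data.frame(
        pair = paste(pr, collapse = "&"), direction = dir,
        entropy = sub$entropy[1],
        improvement_raw = ir$raw, improvement_display = ir$display,
        p_value = pv)
    }
  }
  new("CohortReport", ci = ciTab, comparisons = do.call(rbind, cmp),
      config = list(decomposition = decomposition, entropy = entropy,
                    cutoff = cutoff, K = K, seed = seed))
}
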