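test_that("COP localization maps force imbalance to plate coordinates", {
  # symmetric load sits at the origin
  fp <- ForcePlateSeries(175, 175, 175, 175, fs = 50, L = 11.5)
  cop <- copFromForces(fp)
  expect_equal(copX(cop), 0)
  expect_equal(copY(cop), 0)

  # full single-corner load on the ++ corner maps to (L, L)
  fp <- ForcePlateSeries(0, 0, 0, 700, fs = 50, L = 11.5)
  cop <- copFromForces(fp)
  expect_equal(copX(cop), 11.5)
  expect_equal(copY(cop), 11.5)

  # scale invariance in the total load
  set.seed(1)
  f <- matrix(runif(40, 10, 100), ncol = 4)
  a <- copFromForces(ForcePlateSeries(f[, 1], f[, 2], f[, 3], f[, 4],
                                      fs = 50, L = 10))
  b <- copFromForces(ForcePlateSeries(3 * f[, 1], 3 * f[, 2], 3 * f[, 3],
                                      3 * f[, 4], fs = 50, L = 10))
  expect_equal(copX(a), copX(b))
  expect_equal(copY(a), copY(b))
  # non-negative forces keep the COP inside the [-L, L] square
  expect_true(all(abs(copX(a)) <= 10 + 1e-12))
  expect_true(all(abs(copY(a)) <= 10 + 1e-12))
})

test_that("degenerate zero load is rejected with the sample index", {
  fp <- new("ForcePlateSeries", fs = 50, f1 = c(1, 0), f2 = c(1, 0),
            f3 = c(1, 0), f4 = c(1, 0), L = 10)
  expect_error(copFromForces(fp), "sample\\(s\\) 2")
})

test_that("force inversion round-trips through COP localization exactly", {
  set.seed(42)
  L <- 11.5
  cop <- COPSeries(x = runif(500, -L, L), y = runif(500, -L, L), fs = 50)
  fp <- forcesFromCop(cop, totalWeight = 700, L = L)
  W <- rowSums(forceMatrix(fp))
  expect_equal(W, rep(700, 500))
  expect_true(all(forceMatrix(fp) >= 0))
  back <- copFromForces(fp)
  expect_lt(max(abs(copX(back) - copX(cop))), 1e-9)
  expect_lt(max(abs(copY(back) - copY(cop))), 1e-9)

  # corner target puts all weight on the corner with ++ sign
  corner <- forcesFromCop(COPSeries(L, L, fs = 50), 700, L = L)
  expect_equal(as.numeric(forceMatrix(corner)), c(0, 0, 0, 700))

  expect_error(forcesFromCop(COPSeries(L + 1, 0, fs = 50), 700, L = L),
               "outside")
})

test_that("origin distance is truncated, not rounded, at two decimals", {
  expect_equal(distanceFromOrigin(11.5, 9.5), 14.91)   # sqrt(222.5) = 14.916..
  expect_equal(distanceFromOrigin(5.75, 4.75), 7.45)   # sqrt(55.625) = 7.458..
  expect_equal(distanceFromOrigin(0, 0), 0)
  expect_equal(distanceFromOrigin(3, 4), 5)
})

test_that("static report from noise-free measurements has all-zero ratios", {
  pts <- staticVerificationPoints()
  meas <- genStaticFixture(pts, nRepeats = 5, noiseSd = 0, seed = 1)
  rep <- staticErrorReport(pts, measured = meas[, c("point", "x", "y")])
  expect_equal(unname(staticMeanRatios(rep)), c(0, 0, 0))
  expect_equal(unname(staticMaxErrorDistances(rep)), c(0, 0, 0))
  expect_false(rep@absoluteErrorFlag)
})

test_that("static report computes per-point ratios from raw repeats", {
  pts <- data.frame(x = c(10, -5), y = c(5, -10))
  meas <- data.frame(point = rep(1:2, each = 2),
                     x = c(11, 11, -4, -4), y = c(4, 4, -11, -11))
  rep <- staticErrorReport(pts, measured = meas)
  tab <- staticTable(rep)
  expect_equal(tab$ratio_x, c(10, 20))   # |11-10|/10, |-4+5|/5 in percent
  expect_equal(tab$ratio_y, c(20, 10))
  expect_equal(unname(staticMeanRatios(rep, display = FALSE)[c("x", "y")]),
               c(15, 15))
})

test_that("zero verification coordinate falls back to absolute error", {
  pts <- data.frame(x = c(0, 10), y = c(5, 5))
  meas <- data.frame(point = c(1, 2), x = c(0.4, 10), y = c(5, 5))
  rep <- staticErrorReport(pts, measured = meas)
  expect_true(rep@absoluteErrorFlag)
  expect_equal(staticTable(rep)$ratio_x[1], 0.4)  # absolute cm, flagged
  # zero-coordinate point excluded from the axis mean
  expect_equal(unname(staticMeanRatios(rep, display = FALSE)[["x"]]), 0)
})

test_that("dynamic radius statistic is mean excursion plus SD", {
  circ <- genCircleFixture(radius = 10, revPerS = 0.5, duration = 20,
                           fs = 50, noiseSd = 0)
  expect_equal(dynamicRadiusStat(circ), 10, tolerance = 1e-9)

  # all samples at the center
  expect_equal(dynamicRadiusStat(COPSeries(rep(0, 10), rep(0, 10), fs = 50)), 0)

  # hand-computable: two radii alternating
  cop <- COPSeries(c(1, 2, 1, 2), c(0, 0, 0, 0), fs = 50)
  expect_equal(dynamicRadiusStat(cop), 1.5 + sd(c(1, 2, 1, 2)))

  # noisy circle stays within radius +/- 3 * noise SD
  noisy <- genCircleFixture(radius = 10, revPerS = 0.5, duration = 60,
                            fs = 50, noiseSd = 0.3, seed = 3)
  expect_lt(abs(dynamicRadiusStat(noisy) - 10), 3 * 0.3)
})
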