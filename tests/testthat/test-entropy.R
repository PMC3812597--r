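test_that("coarse-graining averages non-overlapping windows with floor rule", {
  expect_equal(coarseGrain(c(1, 2, 3, 4), 2), c(1.5, 3.5))
  x <- rnorm(100)
  expect_identical(coarseGrain(x, 1), x)             # scale 1 is the identity
  expect_length(coarseGrain(rnorm(7), 3), 2)         # trailing window dropped
  expect_equal(coarseGrain(1:9, 3), c(2, 5, 8))
  expect_error(coarseGrain(rnorm(5), 6), "invalid scale")
})

test_that("sample entropy matches the brute-force oracle", {
  # deterministic alternating series
  x <- rep(c(1, 2), 4)
  expect_equal(as.numeric(sampleEntropy(x, m = 2, r = 0.5)),
               sampenOracle(x, 2, 0.5))
  # random inputs across lengths, tolerances, dimensions
  set.seed(31)
  for (i in 1:20) {
    n <- sample(30:200, 1)
    m <- sample(1:3, 1)
    x <- rnorm(n)
    r <- runif(1, 0.1, 0.4) * sd(x)
    expect_equal(as.numeric(sampleEntropy(x, m, r)), sampenOracle(x, m, r))
  }
})

test_that("sample entropy of white noise is stable and oracle-exact", {
  set.seed(99)
  vals <- vapply(1:20, function(i) {
    x <- rnorm(3000)
    as.numeric(sampleEntropy(x, 2, 0.15 * sd(x)))
  }, numeric(1))
  # theory for N(0,1), m = 2, r = 0.15 sd gives ~2.1-2.3; check stability
  expect_lt(sd(vals), 0.05)
  x <- rnorm(150)
  expect_equal(as.numeric(sampleEntropy(x, 2, 0.15 * sd(x))),
               sampenOracle(x, 2, 0.15 * sd(x)))
})

test_that("sample entropy handles degenerate input", {
  expect_equal(sampleEntropy(rep(3, 50), m = 2, r = 0.1), 0)  # constant
  expect_error(sampleEntropy(c(1, 2, 3), m = 2, r = 0.5), "short")
  # amplitude invariance: scaling series and r together changes nothing
  set.seed(8)
  x <- rnorm(200)
  expect_equal(as.numeric(sampleEntropy(x, 2, 0.2)),
               as.numeric(sampleEntropy(10 * x, 2, 2)))
})

test_that("multivariate sample entropy matches its exhaustive oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(25:120, 1)
    p <- sample(2:3, 1)
    X <- matrix(rnorm(n * p), n)
    r <- runif(1, 0.15, 0.5)
    expect_equal(as.numeric(multivariateSampleEntropy(X, m = 2, r = r)),
                 mvsampenOracle(X, 2, r))
  }
  # short-series case from first principles
  X <- matrix(rnorm(60), 30)
  expect_equal(as.numeric(multivariateSampleEntropy(X, m = 2, r = 0.4)),
               mvsampenOracle(X, 2, 0.4))
})

test_that("multivariate sample entropy is symmetric and handles constants", {
  X <- cbind(rep(1, 40), rep(1, 40))
  expect_equal(multivariateSampleEntropy(X, m = 2, r = 0.2), 0)
  set.seed(23)
  Y <- matrix(rnorm(90), ncol = 3)
  expect_equal(as.numeric(multivariateSampleEntropy(Y, 2, 0.5)),
               as.numeric(multivariateSampleEntropy(Y[, c(3, 1, 2)], 2, 0.5)))
})

test_that("white-noise MSE curves decrease over the first scales", {
  wins <- 0
  for (seed in 1:10) {
    set.seed(seed)
    curve <- mseCurve(rnorm(3000), entropyConfig(maxScale = 5))
    v <- entropyValues(curve)
    if (all(diff(v) < 0)) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("entropy curves sum to the complexity index", {
  expect_equal(complexityIndex(c(1, 0.8, 0.6)), 2.4)
  expect_equal(complexityIndex(c(1, 1, 1, 1)), 4)
  expect_error(complexityIndex(numeric()), "empty")
  # partial curves are flagged
  partial <- complexityIndex(c(1, NA, 0.5))
  expect_equal(as.numeric(partial), 1.5)
  expect_true(attr(partial, "partial"))
  expect_equal(attr(partial, "nDefined"), 2L)

  # constant input gives a zero curve
  curve <- mseCurve(rep(2, 500), entropyConfig(maxScale = 5))
  expect_equal(entropyValues(curve), rep(0, 5))
  expect_equal(complexityIndex(curve), 0)

  # CI additivity over scale ranges
  set.seed(4)
  x <- rnorm(1200)
  c10 <- mseCurve(x, entropyConfig(maxScale = 8))
  c5 <- mseCurve(x, entropyConfig(maxScale = 4))
  expect_equal(complexityIndex(c5) + sum(entropyValues(c10)[5:8]),
               complexityIndex(c10))
})

test_that("mmse orders joint noise above a joint slow oscillation", {
  wins <- 0
  t <- (0:2999) / 50
  for (seed in 1:10) {
    set.seed(seed)
    noiseCI <- complexityIndex(mmseCurve(cbind(rnorm(3000), rnorm(3000))))
    ph <- runif(2, 0, 2 * pi)
    sines <- cbind(sin(2 * pi * 0.3 * t + ph[1]), sin(2 * pi * 0.3 * t + ph[2]))
    sineCI <- complexityIndex(mmseCurve(sines))
    if (noiseCI > sineCI) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("mmse at a single scale equals multivariate sample entropy", {
  set.seed(12)
  X <- matrix(rnorm(500), ncol = 2)
  curve <- mmseCurve(X, entropyConfig(maxScale = 1))
  Z <- scale(X)
  expect_equal(complexityIndex(curve),
               as.numeric(multivariateSampleEntropy(Z, 2, 0.15)))
  # constant channels give a zero curve
  expect_equal(complexityIndex(mmseCurve(cbind(rep(1, 300), rep(2, 300)),
                                         entropyConfig(maxScale = 2))), 0)
})
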