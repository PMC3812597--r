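test_that("direction sets are unit-norm and well spread", {
  d2 <- directionSet(2, 64)
  expect_equal(sqrt(rowSums(d2^2)), rep(1, 64), tolerance = 1e-12)
  ang <- sort(atan2(d2[, 2], d2[, 1]) %% (2 * pi))
  gaps <- diff(c(ang, ang[1] + 2 * pi))
  expect_lt(max(gaps), 2 * (2 * pi / 64))

  d3 <- directionSet(3, 32)
  expect_equal(sqrt(rowSums(d3^2)), rep(1, 32), tolerance = 1e-12)
  # deterministic construction
  expect_identical(directionSet(3, 32), directionSet(3, 32))

  expect_error(directionSet(2, 3), ">= 4")
  expect_error(directionSet(4, 6), "twice")
})

test_that("multivariate mean envelope is small for joint sinusoids and linear", {
  t <- (0:999) / 50
  s <- cbind(sin(2 * pi * 1 * t), sin(2 * pi * 1 * t + 0.7))
  dirs <- directionSet(2, 64)
  env <- multivariateMeanEnvelope(s, dirs)
  expect_true(env$ok)
  interior <- 101:900
  expect_lt(max(abs(env$mean[interior, ])), 0.05)

  # linearity: scaling the signal scales the envelope
  env3 <- multivariateMeanEnvelope(3 * s, dirs)
  expect_equal(env3$mean, 3 * env$mean, tolerance = 1e-10)

  # constant channels classify as residue
  flat <- multivariateMeanEnvelope(cbind(rep(1, 100), rep(2, 100)), dirs)
  expect_false(flat$ok)
})

test_that("memd aligns corresponding IMFs across channels", {
  t <- (0:2999) / 50
  s <- cbind(sin(2 * pi * 0.5 * t) + sin(2 * pi * 8 * t + 0.5),
             sin(2 * pi * 0.5 * t + 1.1) + sin(2 * pi * 8 * t + 2))
  dec <- memd(s, fs = 50)
  expect_gte(nIMF(dec), 2)

  # per-channel reconstruction identity
  for (ch in 1:2) {
    rec <- rowSums(imfMatrix(dec, ch)) + imfResidue(dec, ch)
    expect_lt(max(abs(rec - s[, ch])) / max(abs(s[, ch])), 1e-8)
  }

  # the IMF index capturing 8 Hz is the same in both channels
  fastIdx <- vapply(1:2, function(ch) {
    freqs <- vapply(seq_len(nIMF(dec)), function(j)
      as.numeric(dominantFrequency(imfMatrix(dec, ch)[, j], 50)), numeric(1))
    which.min(abs(freqs - 8))
  }, integer(1))
  expect_equal(fastIdx[1], fastIdx[2])
  f1 <- as.numeric(dominantFrequency(imfMatrix(dec, 1)[, fastIdx[1]], 50))
  f2 <- as.numeric(dominantFrequency(imfMatrix(dec, 2)[, fastIdx[2]], 50))
  expect_lt(max(f1, f2) / min(f1, f2), 1.5)
})

test_that("single-tone channels concentrate variance in the first IMF pair", {
  t <- (0:1499) / 50
  s <- cbind(sin(2 * pi * 2 * t), cos(2 * pi * 2 * t))
  dec <- memd(s, fs = 50)
  for (ch in 1:2) {
    v <- apply(imfMatrix(dec, ch), 2, var)
    expect_gt(v[1] / sum(v), 0.95)
  }
})

test_that("memd rejects NaN input and single channels", {
  expect_error(memd(cbind(c(1, NaN, rnorm(98)), rnorm(100))), "NaN")
  expect_error(memd(matrix(rnorm(100), ncol = 1)), "2 channels")
})

test_that("noise-assisted memd is seeded and validated", {
  cop <- genSway(swayModel(duration = 20, seed = 3))
  a <- naMemd(cop, seed = 11)
  b <- naMemd(cop, seed = 11)
  expect_identical(a@imfs, b@imfs)
  expect_equal(channelNames(a), c("ML", "AP"))

  expect_error(naMemd(cop, noiseSdFraction = 0), "positive")
  expect_error(naMemd(rnorm(100), rnorm(99)), "equal length")
})

test_that("noise assistance resolves mode mixing of an intermittent burst", {
  # slow tone with a high-frequency burst in the middle third
  fs <- 50
  t <- (0:1499) / fs
  tone <- sin(2 * pi * 0.5 * t)
  burst <- sin(2 * pi * 10 * t)
  burst[t < 10 | t > 20] <- 0
  x <- tone + 0.4 * burst
  sepNA <- 0
  sepEMD <- 0
  for (seed in 1:10) {
    dec <- naMemd(x, x + 0, nNoiseChannels = 1, noiseSdFraction = 0.1,
                  seed = seed, fs = fs)
    im <- imfMatrix(dec, 1)
    bIdx <- which.max(abs(apply(im, 2, cor, y = burst)))
    tIdx <- which.max(abs(apply(im, 2, cor, y = tone)))
    if (bIdx != tIdx) sepNA <- sepNA + 1
    ue <- imfMatrix(emd(x, fs = fs))
    if (ncol(ue) >= 2) {
      bU <- which.max(abs(apply(ue, 2, cor, y = burst)))
      tU <- which.max(abs(apply(ue, 2, cor, y = tone)))
      if (bU != tU) sepEMD <- sepEMD + 1
    }
  }
  expect_gte(sepNA, 8)
  expect_gte(sepNA, sepEMD)
})
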