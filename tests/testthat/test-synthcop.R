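test_that("sway model validates its parameters", {
  expect_error(swayModel(duration = 0), "duration")
  expect_error(swayModel(fs = -5), "fs")
  expect_error(swayModel(freqBand = c(2, 1)), "freqBand")
  expect_error(swayModel(freqBand = c(0.1, 30), fs = 50), "Nyquist")
  expect_error(swayModel(regularity = 1.2), "regularity")
  expect_error(swayModel(noiseSd = -1), "non-negative")
})

test_that("a single noiseless oscillator is a pure tone", {
  m <- swayModel(nOscillators = 1, freqBand = c(1 - 1e-9, 1 + 1e-9),
                 noiseSd = 0, duration = 60, fs = 50, seed = 2)
  cop <- genSway(m)
  f <- dominantFrequency(copX(cop), fs = 50)
  expect_equal(as.numeric(f), 1.0, tolerance = 1e-3)
  # mean-removed
  expect_equal(mean(copX(cop)), 0)
  expect_equal(mean(copY(cop)), 0)
})

test_that("generators are bit-identical under a fixed seed", {
  m <- swayModel(seed = 7)
  expect_identical(copX(genSway(m)), copX(genSway(m)))
  expect_identical(genStaticFixture(seed = 5), genStaticFixture(seed = 5))
  a <- genCircleFixture(noiseSd = 0.2, seed = 9)
  b <- genCircleFixture(noiseSd = 0.2, seed = 9)
  expect_identical(copX(a), copX(b))
  c1 <- genCohort(nSubjects = 2, seed = 3)
  c2 <- genCohort(nSubjects = 2, seed = 3)
  expect_identical(subjectSeries(c1, 2)$WPEC@x, subjectSeries(c2, 2)$WPEC@x)
})

test_that("generated sway keeps its power below 2 Hz", {
  m <- swayModel(freqBand = c(0.1, 2.0), fs = 50, duration = 60, seed = 4)
  cop <- genSway(m)
  expect_gte(powerBelow(copX(cop), 50, 2), 0.95)
  expect_gte(powerBelow(copY(cop), 50, 2), 0.95)
})

test_that("cohort structure follows the four-condition protocol", {
  ch <- genCohort(tinyConditions(), nSubjects = 2, seed = 11)
  expect_equal(nSubjects(ch), 2)
  expect_setequal(conditionNames(ch), c("EO", "EC", "WPEO", "WPEC"))
  s1 <- subjectSeries(ch, 1)
  expect_s4_class(s1$WPEO, "COPSeries")
  expect_equal(nSamples(s1$EO), 24 * 50)

  expect_error(genCohort(nSubjects = 0), ">= 1")
  expect_error(genCohort(list(), nSubjects = 2), "non-empty")
  dup <- list(conditionSpec("EO", swayModel()), conditionSpec("EO", swayModel()))
  expect_error(genCohort(dup, nSubjects = 2), "distinct")
})

test_that("water pad scales amplitude and regularity as configured", {
  m <- swayModel(amplitudeScale = 0.4, regularity = 0.35)
  wp <- waterPad(m)
  expect_equal(wp$amplitudeScale, 0.72)
  expect_equal(wp$regularity, 0.50)
  expect_equal(waterPad(swayModel(regularity = 0.9))$regularity, 1)  # clipped

  # water-pad recordings have visibly larger sway
  ch <- genCohort(tinyConditions(), nSubjects = 3, seed = 8)
  sds <- sapply(1:3, function(s) {
    x <- subjectSeries(ch, s)
    c(eo = sd(copX(x$EO)) + sd(copY(x$EO)),
      wp = sd(copX(x$WPEO)) + sd(copY(x$WPEO)))
  })
  expect_true(all(sds["wp", ] > sds["eo", ]))
})

test_that("static fixture reproduces its layout and noise contract", {
  fix <- genStaticFixture(nRepeats = 10, noiseSd = 0, seed = 1)
  expect_equal(nrow(fix), 80)                       # 8 points x 10 repeats
  expect_equal(fix$x, fix$true_x)                   # noiseless == exact
  noisy <- genStaticFixture(nRepeats = 10, noiseSd = 0.3, seed = 2)
  expect_gt(sd(noisy$x - noisy$true_x), 0.2)
})

test_that("circle fixture traces the requested circle", {
  circ <- genCircleFixture(radius = 10, revPerS = 0.5, duration = 10,
                           fs = 50, noiseSd = 0)
  r <- sqrt(copX(circ)^2 + copY(circ)^2)
  expect_equal(r, rep(10, 500), tolerance = 1e-12)
  expect_error(genCircleFixture(radius = -1), "radius")
})
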