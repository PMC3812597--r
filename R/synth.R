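#' Sway model specification
#'
#' Parameter set for the synthetic postural-sway generator. A recording is
#' built from a set of `nOscillators` sinusoidal sway modes with
#' frequencies drawn in `freqBand` and random phases; the two output
#' channels (ML, AP) share this oscillatory drive -- quiet-stance sway is
#' modelled as a common neuromuscular rhythm expressed in both directions
#' -- and differ through their channel weighting and independent Gaussian
#' measurement noise. Channel weights decay geometrically with oscillator
#' index at a rate set by `regularity`: 0 spreads energy across the modes
#' (an irregular, complex sway), 1 concentrates nearly all of it in the
#' first mode (a regular, low-complexity sway). The mixture is normalised
#' so each channel's oscillatory RMS tracks `amplitudeScale`.
#'
#' `regularity` and `amplitudeScale` accept one value (both channels) or
#' two (ML, AP) -- a perturbed stance often expresses its extra regularity
#' unevenly across directions.
#'
#' Defaults emulate quiet-stance recordings: 60 s at 50 Hz, sway energy
#' confined below 2 Hz.
#'
#' @param nOscillators number of sinusoidal sway modes.
#' @param freqBand length-2 numeric, (low, high) frequency bounds in Hz.
#' @param amplitudeScale RMS amplitude of the oscillatory part (cm);
#'   length 1 or 2.
#' @param noiseSd SD of the additive Gaussian noise per channel (cm).
#' @param regularity energy-concentration fraction in \[0, 1\]; length 1
#'   or 2.
#' @param duration recording length (s).
#' @param fs sampling rate (Hz); must exceed twice the upper band edge.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return a validated `SwayModel` (classed list).
#' @export
swayModel <- function(nOscillators = 8, freqBand = c(0.1, 1.5),
                      amplitudeScale = 0.4, noiseSd = 0.01,
                      regularity = 0.35, duration = 60, fs = 50,
                      seed = NULL) {
  assertScalarPositive(duration, "duration")
  assertScalarPositive(fs, "fs")
  assertScalarPositive(nOscillators, "nOscillators")
  if (length(freqBand) != 2L || freqBand[1] >= freqBand[2] || freqBand[1] <= 0)
    stopf("'freqBand' must be (low, high) with 0 < low < high")
  if (fs <= 2 * freqBand[2])
    stopf("'fs' must exceed twice the upper band edge (Nyquist)")
  if (any(noiseSd < 0) || any(amplitudeScale < 0))
    stopf("scales must be non-negative")
  if (any(regularity < 0) || any(regularity > 1))
    stopf("'regularity' must lie in [0, 1]")
  if (length(regularity) > 2L || length(amplitudeScale) > 2L)
    stopf("'regularity' and 'amplitudeScale' take 1 or 2 values")
  structure(list(nOscillators = as.integer(nOscillators),
                 freqBand = as.numeric(freqBand),
                 amplitudeScale = amplitudeScale, noiseSd = noiseSd,
                 regularity = regularity, duration = duration, fs = fs,
                 seed = seed),
            class = "SwayModel")
}

#' Condition specification for a cohort
#'
#' Pairs a condition name from the four-condition balance protocol with
#' the sway model that generates it: EO (eyes open), EC (eyes closed),
#' WPEO / WPEC (the same on a compliant water pad). For water-pad
#' conditions, pass the *base* (unperturbed) model together with
#' `padEffect`; [genCohort()] then applies the pad perturbation per
#' subject, splitting the regularity increase across the ML/AP directions
#' along each subject's own dominant axis (see [genCohort()]).
#'
#' @param name one of `"EO"`, `"EC"`, `"WPEO"`, `"WPEC"`.
#' @param model a [swayModel()] (the base model for pad conditions).
#' @param padEffect `NULL`, or `list(kAmp =, delta =)` -- the water-pad
#'   amplitude multiplier and regularity increment (see [waterPad()]).
#' @return a `ConditionSpec` (classed list).
#' @export
conditionSpec <- function(name, model, padEffect = NULL) {
  name <- match.arg(name, c("EO", "EC", "WPEO", "WPEC"))
  stopifnot(inherits(model, "SwayModel"))
  if (!is.null(padEffect))
    stopifnot(is.list(padEffect), all(c("kAmp", "delta") %in% names(padEffect)))
  structure(list(name = name, model = model, padEffect = padEffect),
            class = "ConditionSpec")
}

#' Apply the water-pad perturbation to a sway model
#'
#' Standing on a compliant pad increases sway amplitude and forces a more
#' regular, effort-driven sway: amplitude is multiplied by `kAmp` and
#' `regularity` increased by `delta` (clipped to 1). The net effect is a
#' larger but less complex sway, hence a lower complexity index.
#'
#' @param model a [swayModel()].
#' @param kAmp amplitude multiplier (default 1.8).
#' @param delta regularity increment (default 0.15).
#' @return a perturbed `SwayModel`.
#' @export
waterPad <- function(model, kAmp = 1.8, delta = 0.15) {
  model$amplitudeScale <- model$amplitudeScale * kAmp
  model$regularity <- pmin(1, model$regularity + delta)
  model
}

#' Default four-condition cohort specification
#'
#' Eyes-open and eyes-closed base models (eyes closed sways slightly more
#' and slightly more regularly), with the water-pad conditions declared
#' via `padEffect` so [genCohort()] can apply the perturbation per
#' subject.
#'
#' @param duration,fs recording length (s) and sampling rate (Hz).
#' @param kAmp,delta water-pad effect sizes (see [waterPad()]).
#' @return list of four [conditionSpec()] objects named EO, EC, WPEO, WPEC.
#' @export
defaultConditions <- function(duration = 60, fs = 50, kAmp = 1.8, delta = 0.15) {
  eo <- swayModel(amplitudeScale = 0.40, regularity = 0.35,
                  duration = duration, fs = fs)
  ec <- swayModel(amplitudeScale = 0.55, regularity = 0.40,
                  duration = duration, fs = fs)
  pad <- list(kAmp = kAmp, delta = delta)
  list(EO = conditionSpec("EO", eo),
       EC = conditionSpec("EC", ec),
       WPEO = conditionSpec("WPEO", eo, padEffect = pad),
       WPEC = conditionSpec("WPEC", ec, padEffect = pad))
}

# Both sway channels under an active RNG stream: a shared oscillatory
# drive (one frequency/phase draw), channel-specific decay weights and
# independent noise. RNG order: frequencies, phases, ML noise, AP noise.
.swayChannels <- function(model) {
  n <- round(model$duration * model$fs)
  t <- (seq_len(n) - 1) / model$fs
  k <- model$nOscillators
  if (!is.null(model$toneSet)) {
    freqs <- model$toneSet$freqs
    phases <- model$toneSet$phases
  } else {
    freqs <- stats::runif(k, model$freqBand[1], model$freqBand[2])
    phases <- stats::runif(k, 0, 2 * pi)
  }
  reg <- rep(model$regularity, length.out = 2)
  amp <- rep(model$amplitudeScale, length.out = 2)
  S <- vapply(seq_len(k), function(j) sin(2 * pi * freqs[j] * t + phases[j]),
              numeric(n))
  ch <- function(c) {
    decay <- 1 - 0.9 * reg[c]
    w <- decay^(seq_len(k) - 1)
    a <- amp[c] * sqrt(2) * w / sqrt(sum(w^2))
    x <- drop(S %*% a) + stats::rnorm(n, 0, model$noiseSd)
    x - mean(x)
  }
  x <- ch(1)
  y <- ch(2)
  list(x = x, y = y)
}

#' Generate a synthetic two-channel sway recording
#'
#' Draws the ML and AP channels of a [swayModel()]: a shared band-limited
#' oscillatory drive weighted per channel, plus independent Gaussian
#' noise, mean-removed. Identical model and seed give bit-identical
#' output.
#'
#' @param model a [swayModel()].
#' @return a [COPSeries-class].
#' @examples
#' cop <- genSway(swayModel(seed = 1))
#' nSamples(cop)  # 3000
#' @export
genSway <- function(model) {
  stopifnot(inherits(model, "SwayModel"))
  withSeed(model$seed, {
    p <- .swayChannels(model)
    COPSeries(x = p$x, y = p$y, fs = model$fs)
  })
}

#' Generate a synthetic sway cohort
#'
#' Per-subject, per-condition COP recordings with subject-level random
#' effects:
#' * a log-normal amplitude factor (`ampFactorSd` on the log scale) and
#'   an additive regularity shift (`regShiftSd`, clipped to \[0, 1\])
#'   applied to every condition;
#' * a direction balance \eqn{\beta \sim U(0, 1)} governing how the
#'   water-pad effect expresses across directions: the ML channel
#'   receives the regularity increment \eqn{2\beta\,\delta} and amplitude
#'   factor \eqn{k^{2\beta}}, the AP channel \eqn{2(1-\beta)\,\delta} and
#'   \eqn{k^{2(1-\beta)}}, so the effect averages to (`delta`, `kAmp`)
#'   per channel over subjects but each subject stiffens mostly along
#'   their own dominant axis;
#' * a recording-level per-channel regularity jitter (`regJitterSd`),
#'   the test-to-test variability of sway regularity in each direction.
#'
#' Water-pad conditions therefore have systematically larger amplitude
#' and higher (joint) regularity than their base conditions within every
#' subject -- hence a lower expected complexity index -- while the
#' per-direction expression of the effect varies between subjects, as it
#' does across real subjects. All randomness descends from `seed` via a
#' subject -> condition -> component splitting scheme.
#'
#' @param conditions named list of [conditionSpec()] objects (default
#'   [defaultConditions()]); names must be distinct.
#' @param nSubjects number of subjects (>= 1).
#' @param seed integer seed.
#' @param ampFactorSd,regShiftSd subject-effect SDs.
#' @param regJitterSd recording-level per-channel regularity jitter SD.
#' @return a [SwayCohort-class].
#' @export
genCohort <- function(conditions = defaultConditions(), nSubjects = 20,
                      seed = 1, ampFactorSd = 0.2, regShiftSd = 0.05,
                      regJitterSd = 0) {
  if (length(conditions) == 0L) stopf("'conditions' must be non-empty")
  if (nSubjects < 1L) stopf("'nSubjects' must be >= 1")
  condNames <- vapply(conditions, `[[`, character(1), "name")
  if (anyDuplicated(condNames)) stopf("condition names must be distinct")
  series <- withSeed(seed, {
    lapply(seq_len(nSubjects), function(s) {
      ampFactor <- exp(stats::rnorm(1, 0, ampFactorSd))
      regShift <- stats::rnorm(1, 0, regShiftSd)
      b <- stats::runif(1)
      split <- 2 * c(b, 1 - b)
      tones <- list(freqs = stats::runif(conditions[[1L]]$model$nOscillators,
                                         conditions[[1L]]$model$freqBand[1],
                                         conditions[[1L]]$model$freqBand[2]),
                    phases = stats::runif(conditions[[1L]]$model$nOscillators,
                                          0, 2 * pi))
      out <- lapply(conditions, function(cs) {
        m <- cs$model
        reg <- rep(m$regularity, length.out = 2) + regShift +
          stats::rnorm(2, 0, regJitterSd)
        amp <- rep(m$amplitudeScale, length.out = 2) * ampFactor
        if (!is.null(cs$padEffect)) {
          reg <- reg + cs$padEffect$delta * split
          amp <- amp * cs$padEffect$kAmp
        }
        m$regularity <- pmin(1, pmax(0, reg))
        m$amplitudeScale <- amp
        m$toneSet <- tones
        m$seed <- sample.int(.Machine$integer.max - 1L, 1)
        genSway(m)
      })
      names(out) <- condNames
      out
    })
  })
  new("SwayCohort", series = series, conditions = condNames,
      seed = as.integer(seed))
}

#' Force channels consistent with a target COP trajectory
#'
#' Inverts the COP localisation formula. The inversion is underdetermined
#' (three constraints, four unknowns); the package adopts the unique
#' bilinear corner weighting that is exact and non-negative on the closed
#' \eqn{[-L, L]} square: with \eqn{u = x/L}, \eqn{v = y/L},
#' \deqn{f_1 = W(1-u)(1-v)/4,\; f_2 = W(1+u)(1-v)/4,}
#' \deqn{f_3 = W(1-u)(1+v)/4,\; f_4 = W(1+u)(1+v)/4.}
#' The four channels sum to `totalWeight` at every sample and
#' [copFromForces()] recovers the input exactly.
#'
#' @param cop a [COPSeries-class]; every sample must satisfy
#'   \eqn{|x| \le L}, \eqn{|y| \le L}.
#' @param totalWeight total vertical load W (force units, e.g. N).
#' @param L plate geometry constant (cm).
#' @return a [ForcePlateSeries-class].
#' @export
forcesFromCop <- function(cop, totalWeight = 700, L = 11.5) {
  stopifnot(is(cop, "COPSeries"))
  assertScalarPositive(totalWeight, "totalWeight")
  assertScalarPositive(L, "L")
  if (any(abs(cop@x) > L) || any(abs(cop@y) > L))
    stopf("COP outside the [-L, L] square (L = %g cm)", L)
  u <- cop@x / L
  v <- cop@y / L
  W <- totalWeight
  ForcePlateSeries(f1 = W * (1 - u) * (1 - v) / 4,
                   f2 = W * (1 + u) * (1 - v) / 4,
                   f3 = W * (1 - u) * (1 + v) / 4,
                   f4 = W * (1 + u) * (1 + v) / 4,
                   fs = cop@fs, L = L)
}

#' Canonical eight-point static verification layout
#'
#' The symmetric eight-location grid used for static point-load
#' verification of a square platform: the four quadrant corners at
#' (±11.5, ±9.5) cm and the four mid positions at (±5.75, ±4.75) cm.
#'
#' @return data.frame with columns `x`, `y` (cm).
#' @export
staticVerificationPoints <- function() {
  data.frame(x = c(11.5, 5.75, 11.5, 5.75, -5.75, -11.5, -5.75, -11.5),
             y = c(9.5, 4.75, -9.5, -4.75, 4.75, 9.5, -4.75, -9.5))
}

#' Generate a static point-load measurement fixture
#'
#' Repeated noisy location measurements for each verification point, as
#' produced by placing a rigid mass at known plate locations.
#'
#' @param points data.frame with columns `x`, `y` (cm); default the
#'   canonical eight-point layout.
#' @param nRepeats measurements per point.
#' @param noiseSd SD of the Gaussian measurement noise per axis (cm).
#' @param seed integer seed.
#' @return data.frame: `point`, `rep`, `true_x`, `true_y`, `x`, `y`.
#' @export
genStaticFixture <- function(points = staticVerificationPoints(),
                             nRepeats = 10, noiseSd = 0.3, seed = 1) {
  stopifnot(is.data.frame(points), nRepeats >= 1)
  np <- nrow(points)
  withSeed(seed, {
    data.frame(
      point = rep(seq_len(np), each = nRepeats),
      rep = rep(seq_len(nRepeats), np),
      true_x = rep(points$x, each = nRepeats),
      true_y = rep(points$y, each = nRepeats),
      x = rep(points$x, each = nRepeats) + stats::rnorm(np * nRepeats, 0, noiseSd),
      y = rep(points$y, each = nRepeats) + stats::rnorm(np * nRepeats, 0, noiseSd))
  })
}

#' Generate a circular dynamic-test fixture
#'
#' Emulates the mechanically driven circular COP displacement used to
#' validate dynamic accuracy: a trajectory at constant angular velocity on
#' a circle of the given radius, with radial Gaussian noise.
#'
#' @param radius circle radius (cm), default the 10 cm test circle.
#' @param revPerS revolutions per second.
#' @param duration recording length (s).
#' @param fs sampling rate (Hz).
#' @param noiseSd SD of the radial noise (cm).
#' @param seed integer seed.
#' @return a [COPSeries-class] centred on the origin.
#' @export
genCircleFixture <- function(radius = 10, revPerS = 0.5, duration = 60,
                             fs = 50, noiseSd = 0, seed = 1) {
  assertScalarPositive(radius, "radius")
  assertScalarPositive(duration, "duration")
  assertScalarPositive(fs, "fs")
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  withSeed(seed, {
    r <- radius + stats::rnorm(n, 0, noiseSd)
    th <- 2 * pi * revPerS * t
    COPSeries(x = r * cos(th), y = r * sin(th), fs = fs)
  })
}
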