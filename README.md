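# copbalance

Balance complexity analysis of center-of-pressure (COP) signals from
four-load-cell force platforms.

Standing balance leaves a signature in the wandering of the center of
pressure under the feet. `copbalance` turns raw corner-load-cell forces
into that trajectory, isolates the physiological sway band, and
condenses it into a single **complexity index (CI)** — the area under a
multiscale sample-entropy curve. A challenged stance (eyes closed,
compliant surface) produces larger but *more regular* sway, hence a
lower CI; comparing CI across test conditions quantifies how strongly a
perturbation degrades balance control.

## What the package does

* **COP localisation** — `copFromForces()` implements
  `X = [(F4+F2) − (F1+F3)]·L/W`, `Y = [(F3+F4) − (F1+F2)]·L/W`
  for a square plate with geometry constant `L`; `forcesFromCop()`
  inverts it exactly with non-negative bilinear corner weights.
* **Device validation** — static point-load error reports
  (`staticErrorReport()`), the mean + SD radius statistic for a driven
  circular displacement (`dynamicRadiusStat()`), lagged cross-correlation
  between devices (`maxCrossCorrelation()`), and ICC(2,1) reliability
  with the conventional 0.75 / 0.4 classification (`icc()`).
* **Decomposition** — empirical mode decomposition (`emd()`), its
  multivariate extension with Hammersley direction sets (`memd()`), and
  noise-assisted MEMD (`naMemd()`) that suppresses mode mixing by adding
  white-noise channels.
* **Band selection** — per-IMF dominant frequencies
  (`dominantFrequency()`, `imfFrequencyTable()`) and reconstruction of
  the sub-2 Hz sway band (`selectBand()`).
* **Entropy** — sample entropy, multiscale entropy, multivariate
  (joint ML&AP) multiscale entropy, and the complexity index
  (`sampleEntropy()`, `mseCurve()`, `mmseCurve()`, `complexityIndex()`),
  with exact C++ template-counting kernels.
* **Synthetic cohorts** — a seeded generator for the four-condition
  protocol (eyes open / closed × with / without a water pad)
  (`swayModel()`, `genCohort()`), plus static and circular calibration
  fixtures, so the entire pipeline is testable end-to-end without human
  recordings.
* **Cohort comparison** — `runCohortPipeline()` reports per-subject CI
  and condition-pair improvement rates with exact Wilcoxon signed-rank
  tests, per direction (MSE) and jointly (MMSE).

## Worked example

```r
library(copbalance)

## a synthetic quiet-stance recording: 60 s at 50 Hz
cop <- genSway(swayModel(seed = 1))
cop
#> COPSeries: 3000 samples at 50 Hz (60.0 s)
#>   ML (x): mean -0.000 cm, SD 0.402 cm
#>   AP (y): mean 0.000 cm, SD 0.403 cm

## decompose jointly with one white-noise assist channel,
## keep the sub-2 Hz IMFs
dec <- naMemd(cop, seed = 2)
sel <- selectBand(dec, cutoff = 2)
selectedIndices(sel)
#> [1] 3 4 5 6 7

## joint ML&AP complexity index
curve <- mmseCurve(reconstructedSignal(sel))
round(complexityIndex(curve), 3)
#> [1] 7.967
```

The entropy curve holds one value per coarse-graining scale (1–10); the
CI is their sum. Lower CI = more regular, less complex sway. On the
bundled static calibration table of a prototype plate:

```r
cal <- bundledStaticCalibration()
staticMeanRatios(staticErrorReport(cal$verification, ratios = cal$ratios))
#>        x        y distance
#>      7.5     11.5      9.0
```

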