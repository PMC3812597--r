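# Shared signal builders for the test suite.

sineWave <- function(freq, fs = 50, duration = 60, phase = 0, amp = 1) {
  t <- (seq_len(round(fs * duration)) - 1) / fs
  amp * sin(2 * pi * freq * t + phase)
}

twoToneSignal <- function(fs = 50, duration = 60, fLow = 0.5, fHigh = 8) {
  list(low = sineWave(fLow, fs, duration),
       high = sineWave(fHigh, fs, duration),
       fs = fs)
}

# Fraction of FFT power at frequencies strictly below `cutoff`.
powerBelow <- function(x, fs, cutoff) {
  n <- length(x)
  pw <- Mod(stats::fft(x - mean(x)))^2
  half <- pw[2:(n %/% 2 + 1)]
  freqs <- seq_along(half) * fs / n
  sum(half[freqs < cutoff]) / sum(half)
}

# Brute-force sample entropy oracle: direct template enumeration,
# independent of the compiled kernel.
sampenOracle <- function(x, m, r, delay = 1) {
  n <- length(x)
  nt <- n - m * delay
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      im <- i + (0:(m - 1)) * delay
      jm <- j + (0:(m - 1)) * delay
      if (max(abs(x[im] - x[jm])) <= r) {
        B <- B + 1
        if (abs(x[i + m * delay] - x[j + m * delay]) <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Brute-force multivariate sample entropy oracle: builds every composite
# delay vector and every pooled extension explicitly.
mvsampenOracle <- function(X, m, r, delay = 1) {
  n <- nrow(X); p <- ncol(X)
  nt <- n - m * delay
  comp <- t(vapply(seq_len(nt), function(i) {
    as.numeric(X[i + rep(0:(m - 1), p) * delay +
                   rep(0, m * p), , drop = FALSE][cbind(rep(1:m, p) +
                     0 * delay, rep(1:p, each = m))])
  }, numeric(m * p)))
  # build composite vectors plainly (loop form, kept independent)
  comp <- matrix(0, nt, m * p)
  for (i in seq_len(nt))
    for (c in seq_len(p))
      for (q in seq_len(m))
        comp[i, (c - 1) * m + q] <- X[i + (q - 1) * delay, c]
  B <- 0
  for (i in seq_len(nt - 1))
    for (j in (i + 1):nt)
      if (max(abs(comp[i, ] - comp[j, ])) <= r) B <- B + 1
  ext <- matrix(0, nt * p, m * p + 1)
  k <- 0
  for (i in seq_len(nt))
    for (e in seq_len(p)) {
      k <- k + 1
      ext[k, ] <- c(comp[i, ], X[i + m * delay, e])
    }
  A <- 0
  for (i in seq_len(nrow(ext) - 1))
    for (j in (i + 1):nrow(ext))
      if (max(abs(ext[i, ] - ext[j, ])) <= r) A <- A + 1
  if (A == 0 || B == 0) return(NA_real_)
  aF <- A / (nrow(ext) * (nrow(ext) - 1) / 2)
  bF <- B / (nt * (nt - 1) / 2)
  -log(aF / bF)
}

# Small, fast cohort settings for pipeline mechanics tests (not the study
# conditions; those are the package defaults).
tinyConditions <- function(duration = 24, fs = 50) {
  eo <- swayModel(amplitudeScale = 0.4, regularity = 0.35,
                  duration = duration, fs = fs)
  ec <- swayModel(amplitudeScale = 0.55, regularity = 0.4,
                  duration = duration, fs = fs)
  list(EO = conditionSpec("EO", eo),
       EC = conditionSpec("EC", ec),
       WPEO = conditionSpec("WPEO", waterPad(eo)),
       WPEC = conditionSpec("WPEC", waterPad(ec)))
}
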