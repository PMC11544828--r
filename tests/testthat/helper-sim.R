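# Shared fixtures: all built in code at test time.

# Cohort without device/termination flags.
quietCohort <- function(n, seed = 1L, ...) {
  generateCohort(cohortSpec(n = n, nPremature = 0L, nBattery = 0L,
                            seed = seed, ...))
}

# Fully deterministic simulator configurations.
noiseFreeScg <- function(...) {
  scgSimConfig(noiseSd = 0, jitterSd = 0, hrNoiseSd = 0, ...)
}
noiseFreeCpet <- function(...) {
  cpetSimConfig(vo2NoiseSd = 0, hrNoiseSd = 0, breathIntervalSd = 0, ...)
}

# Recording assembled from B copies of an arbitrary beat template at a fixed
# inter-beat spacing, plus optional white noise. The spacing 2.56 s makes the
# 0-80% beat window an exact multiple of the sampling interval, so the
# resampling grid coincides with native samples and noise statistics carry
# through the ensemble average unchanged.
templateRecording <- function(template, B = 40L, fs = 250, spacing = 2.56,
                              noiseSd = 0, lead = 0.5) {
  nT <- length(template)
  dur <- lead + B * spacing + 1
  x <- numeric(round(dur * fs))
  fid <- lead + (seq_len(B) - 1L) * spacing
  for (f in fid) {
    i <- round(f * fs) + seq_len(nT)
    x[i] <- x[i] + template
  }
  if (noiseSd > 0) x <- x + stats::rnorm(length(x), 0, noiseSd)
  new("SCGRecording", samples = x, fs = fs, fiducials = fid,
      condition = "rest", meta = list())
}

# A smooth asymmetric beat template over `sec` seconds.
demoTemplate <- function(fs = 250, sec = 2.3) {
  t <- seq(0, sec, by = 1 / fs)[-1]
  exp(-((t - 0.1) / 0.03)^2) * cos(2 * pi * 22 * (t - 0.1)) +
    0.6 * exp(-((t - 1.5) / 0.08)^2) * cos(2 * pi * 8 * (t - 1.5))
}

# Random regression design matching the SCG model's predictor layout, with
# a fixed ground-truth coefficient vector for recovery tests.
randomDesign <- function(n, seed) {
  set.seed(seed)
  data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 48, 9),
             weight = rnorm(n, 76, 14), height = rnorm(n, 1.77, 0.08),
             rr_ms = rnorm(n, 1000, 120), dia_ptp = rnorm(n, 0.7, 0.1),
             dia_morph = rnorm(n), sys_spec = rnorm(n))
}

trueBeta <- c(intercept = 40, sex = -6, age = -0.3, weight = -0.05,
              height = 5, rr_ms = 0.01, dia_ptp = 12, dia_morph = 1.5,
              sys_spec = 0.8)

linResponse <- function(d, beta = trueBeta) {
  as.numeric(cbind(1, as.matrix(d)) %*% beta)
}

# Independent ICC oracle: two-way crossed ANOVA mean squares obtained from
# stats::aov on the long-format data, then the absolute-agreement formula.
iccOracleAov <- function(mat) {
  n <- nrow(mat)
  k <- ncol(mat)
  long <- data.frame(y = as.vector(mat),
                     subj = factor(rep(seq_len(n), k)),
                     meas = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(y ~ subj + meas, data = long))[[1L]]
  msr <- tab["subj", "Mean Sq"]
  msc <- tab["meas", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# Feature table for a cohort of noise-free rest recordings (one per
# subject), processed through the full detection -> ensemble -> basis ->
# extraction chain.
cohortFeatures <- function(cohort, cfg = noiseFreeScg(), seedBase = 100L,
                           detect = FALSE) {
  beats <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- simulateScg(cohort[i, ], "rest", cfg, seed = seedBase + i)
    if (detect) rec@fiducials <- NULL
    ensembleAverage(rec)
  })
  basis <- fitFeatureBasis(beats)
  ft <- do.call(rbind, lapply(beats, extractFeatures, basis = basis))
  ft$true_vo2max_rel <- cohort$true_vo2max_rel
  list(features = ft, beats = beats, basis = basis)
}
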