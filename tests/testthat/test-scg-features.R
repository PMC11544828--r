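# SCG processing: beat detection, ensemble averaging, PCA basis, features.

test_that("noise-free detection lands on the true fiducials", {
  subj <- quietCohort(1, seed = 3)[1, ]
  rec <- simulateScg(subj, "rest", noiseFreeScg(), seed = 1)
  truth <- fiducialTimes(rec)
  rec@fiducials <- NULL
  det <- detectBeats(rec)
  matched <- vapply(truth, function(f) min(abs(det - f)), numeric(1))
  expect_true(all(matched <= 1 / sampleRate(rec) + 1e-9))
})

test_that("recordings with fiducials bypass detection unchanged", {
  subj <- quietCohort(1, seed = 4)[1, ]
  rec <- simulateScg(subj, "rest", scgSimConfig(), seed = 2)
  expect_identical(detectBeats(rec), fiducialTimes(rec))
})

test_that("detection matches >=95% of beats within 50 ms at default noise", {
  co <- quietCohort(5, seed = 5)
  hits <- vapply(seq_len(5), function(i) {
    rec <- simulateScg(co[i, ], "rest", scgSimConfig(), seed = 10 + i)
    truth <- fiducialTimes(rec)
    rec@fiducials <- NULL
    det <- detectBeats(rec)
    mean(vapply(truth, function(f) min(abs(det - f)) < 0.05, logical(1)))
  }, numeric(1))
  expect_true(all(hits >= 0.95))
})

test_that("detection refuses short or beat-poor recordings", {
  rec <- new("SCGRecording", samples = rnorm(250 * 5), fs = 250,
             fiducials = NULL, condition = "rest", meta = list())
  expect_error(detectBeats(rec), "10 s")
  flat <- new("SCGRecording", samples = rnorm(250 * 42, sd = 1e-4), fs = 250,
              fiducials = NULL, condition = "rest", meta = list())
  expect_error(ensembleAverage(flat), "quality error")
})

test_that("ensemble noise reduction follows sigma/sqrt(B)", {
  tmpl <- demoTemplate()
  clean <- ensembleAverage(templateRecording(tmpl, B = 40L))
  sigma <- 0.1
  set.seed(99)
  resid <- replicate(100, {
    noisy <- ensembleAverage(templateRecording(tmpl, B = 40L,
                                               noiseSd = sigma))
    sd(waveform(noisy) - waveform(clean))
  })
  expect_equal(mean(resid), sigma / sqrt(40), tolerance = 0.2)
})

test_that("an inverted-polarity beat is rejected from the ensemble", {
  tmpl <- demoTemplate()
  rec <- templateRecording(tmpl, B = 41L)
  # invert beat 20 in place
  f <- fiducialTimes(rec)[20]
  i <- round(f * sampleRate(rec)) + seq_along(tmpl)
  x <- samples(rec)
  x[i] <- x[i] - 2 * tmpl
  rec@samples <- x
  eb <- ensembleAverage(rec)
  expect_equal(nBeatsRejected(eb), 1L)
  expect_equal(nBeatsUsed(eb), 40L)
})

test_that("first principal component matches the hand-worked 2x2 case", {
  # two 'waveforms' (0,1) and (0,3): all variance on coordinate 2
  pc <- scgvo2:::firstPC(matrix(c(0, 0, 1, 3), nrow = 2))
  expect_equal(abs(as.numeric(pc$loading)), c(0, 1), tolerance = 1e-12)
})

test_that("basis fitting is deterministic and rejects degenerate input", {
  co <- quietCohort(12, seed = 6)
  beats <- cohortFeatures(co)$beats
  b1 <- fitFeatureBasis(beats)
  b2 <- fitFeatureBasis(beats)
  expect_equal(b1@diaLoadings, b2@diaLoadings)
  expect_equal(b1@sysLoadings, b2@sysLoadings)
  expect_equal(sum(b1@diaLoadings^2), 1, tolerance = 1e-9)
  expect_equal(sum(b1@sysLoadings^2), 1, tolerance = 1e-9)
  expect_error(fitFeatureBasis(beats[1:5]), "at least 10")
  expect_error(fitFeatureBasis(rep(beats[1], 12)), "zero-variance")
})

test_that("training scores are centered and follow the sign convention", {
  co <- quietCohort(40, seed = 16)
  cf <- cohortFeatures(co, noiseFreeScg(restHrSd = 0))
  expect_equal(mean(cf$features$dia_morph), 0, tolerance = 1e-8)
  expect_equal(mean(cf$features$sys_spec), 0, tolerance = 1e-8)
  # positive orientation: scores rise with fitness by construction of the
  # generator (higher systolic frequency, faster diastolic template)
  expect_gt(cor(cf$features$sys_spec, co$true_vo2max_rel), 0)
  expect_gt(cor(cf$features$dia_morph, co$true_vo2max_rel), 0)
})

test_that("feature extraction has the stated degeneracies", {
  co <- quietCohort(12, seed = 26)
  cf <- cohortFeatures(co)
  beat <- cf$beats[[1]]
  f1 <- extractFeatures(beat, cf$basis)

  flat <- beat
  flat@waveform <- numeric(length(waveform(beat)))
  expect_equal(extractFeatures(flat, cf$basis)$dia_ptp, 0)

  doubled <- beat
  doubled@waveform <- 2 * waveform(beat)
  f2 <- extractFeatures(doubled, cf$basis)
  expect_equal(f2$dia_ptp, 2 * f1$dia_ptp)
  expect_equal(f2$rr_ms, f1$rr_ms)
})

test_that("noise-free extracted peak-to-peak matches the generator value", {
  co <- quietCohort(15, seed = 36)
  cfg <- noiseFreeScg()
  truth <- vapply(seq_len(nrow(co)), function(i)
    simulateScg(co[i, ], "rest", cfg, seed = 50 + i)@meta$dia_ptp,
    numeric(1))
  ft <- cohortFeatures(co, cfg, seedBase = 50L)$features
  expect_equal(ft$dia_ptp, truth, tolerance = 0.02)
})

test_that("whole-sample time shifts leave the features unchanged", {
  co <- quietCohort(12, seed = 46)
  cf <- cohortFeatures(co)
  rec <- simulateScg(co[1, ], "rest", noiseFreeScg(), seed = 51)
  for (k in c(3L, 40L)) {
    shifted <- new("SCGRecording",
                   samples = c(numeric(k), samples(rec)),
                   fs = sampleRate(rec),
                   fiducials = fiducialTimes(rec) + k / sampleRate(rec),
                   condition = "rest", meta = list())
    f0 <- extractFeatures(ensembleAverage(rec), cf$basis)
    f1 <- extractFeatures(ensembleAverage(shifted), cf$basis)
    expect_equal(f1, f0, tolerance = 1e-10)
  }
})

test_that("noise-free feature coupling to fitness is strictly monotone", {
  co <- quietCohort(25, seed = 56)
  ft <- cohortFeatures(co, noiseFreeScg(restHrSd = 0))$features
  v <- ft$true_vo2max_rel
  expect_equal(cor(v, ft$dia_ptp, method = "spearman"), 1)
  expect_equal(cor(v, ft$sys_spec, method = "spearman"), 1)
})
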