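# Synthetic-data module: cohorts, SCG recordings, CPET traces.

test_that("cohort generation is deterministic and honours the spec", {
  spec <- cohortSpec(n = 50, nPremature = 5L, nBattery = 2L, seed = 42)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 50L)
  expect_equal(sum(a$premature_termination), 5L)
  expect_equal(sum(a$battery_failure), 2L)
  expect_false(any(a$premature_termination & a$battery_failure))
  expect_true(all(a$age > 0))
  expect_true(all(a$height > 1.2 & a$height < 2.2))
  expect_true(all(a$weight > 30))
  expect_true(all(a$true_vo2max_rel > 10 & a$true_vo2max_rel < 90))
})

test_that("cohort rejects invalid specs with the field named", {
  expect_error(cohortSpec(n = 0), "n")
  expect_error(cohortSpec(sexFemaleProb = 1.2), "sexFemaleProb")
  expect_error(cohortSpec(ageSd = -1), "ageSd")
  expect_error(cohortSpec(n = 5, nPremature = 4L, nBattery = 3L),
               "nPremature")
})

test_that("large cohorts reproduce the target demographic mix", {
  co <- quietCohort(2000, seed = 9)
  expect_equal(mean(co$sex), 0.521, tolerance = 0.05)
  expect_equal(mean(co$age), 48.2, tolerance = 0.02)
  expect_equal(mean(co$weight), 76.5, tolerance = 0.02)
  expect_equal(mean(co$true_vo2max_rel), 37.2, tolerance = 0.03)
  expect_equal(sd(co$true_vo2max_rel), 8.6, tolerance = 0.08)
  gap <- mean(co$true_vo2max_rel[co$active_lifestyle]) -
    mean(co$true_vo2max_rel[!co$active_lifestyle])
  expect_equal(gap, 10, tolerance = 0.1)
})

test_that("SCG simulation is deterministic and beat rate follows the config", {
  subj <- quietCohort(1, seed = 3)[1, ]
  subj$true_vo2max_rel <- 37.2  # isolate the HR intercept
  cfg <- noiseFreeScg(restHrSd = 0)
  a <- simulateScg(subj, "rest", cfg, seed = 5)
  b <- simulateScg(subj, "rest", cfg, seed = 5)
  expect_identical(samples(a), samples(b))
  expect_identical(fiducialTimes(a), fiducialTimes(b))
  # rest_hr_mean 60.1 BPM -> mean beat interval ~ 1.0 s
  expect_equal(mean(diff(fiducialTimes(a))), 1.0, tolerance = 0.02)
  expect_equal(length(samples(a)), round(42 * 250))
})

test_that("noise-free beats are identical and the ensemble equals one beat", {
  subj <- quietCohort(1, seed = 7)[1, ]
  rec <- simulateScg(subj, "rest", noiseFreeScg(), seed = 1)
  bm <- scgvo2:::beatMatrix(rec, fiducialTimes(rec), scgWindows())
  for (i in seq_len(nrow(bm$mat)))
    expect_equal(bm$mat[i, ], bm$mat[1L, ], tolerance = 1e-12)
  eb <- ensembleAverage(rec)
  expect_equal(waveform(eb), unname(bm$mat[1L, ]), tolerance = 1e-12)
  expect_equal(nBeatsRejected(eb), 0L)
})

test_that("diastolic amplitude increases strictly with fitness", {
  co <- quietCohort(2, seed = 11)
  co$true_vo2max_rel <- c(30, 50)
  r1 <- simulateScg(co[1, ], "rest", noiseFreeScg(), seed = 1)
  r2 <- simulateScg(co[2, ], "rest", noiseFreeScg(), seed = 1)
  expect_gt(r2@meta$dia_ptp, r1@meta$dia_ptp)
  expect_gt(r2@meta$sys_freq, r1@meta$sys_freq)
})

test_that("undersampled systolic band raises a configuration error", {
  subj <- quietCohort(1, seed = 2)[1, ]
  subj$true_vo2max_rel <- 80
  cfg <- scgSimConfig(fs = 100, sysCenterFreqBase = 40, sysFreqSlope = 0.2)
  expect_error(simulateScg(subj, "rest", cfg, seed = 1), "representable")
})

test_that("post-exercise beat rate exceeds rest beat rate cohort-wide", {
  co <- quietCohort(50, seed = 21)
  cfg <- scgSimConfig()
  hr <- vapply(seq_len(nrow(co)), function(i) {
    r <- simulateScg(co[i, ], "rest", cfg, seed = 100 + i)
    p <- simulateScg(co[i, ], "post_exercise", cfg, seed = 200 + i)
    c(r@meta$hr, p@meta$hr)
  }, numeric(2L))
  expect_gt(mean(hr[2, ]), mean(hr[1, ]))
  expect_equal(mean(hr[1, ]), 60.1, tolerance = 0.1)
  expect_equal(mean(hr[2, ]), 82.0, tolerance = 0.1)
})

test_that("subject-level heart rate is stable across repeat recordings", {
  subj <- quietCohort(1, seed = 13)[1, ]
  cfg <- noiseFreeScg()
  a <- simulateScg(subj, "rest", cfg, seed = 1)
  b <- simulateScg(subj, "rest", cfg, seed = 999)
  expect_equal(a@meta$hr, b@meta$hr, tolerance = 1e-12)
})

test_that("CPET traces end exhausted unless flagged, and flags propagate", {
  co <- quietCohort(5, seed = 31)
  for (i in seq_len(5)) {
    tr <- simulateCpet(co[i, ], cpetSimConfig(), seed = 40 + i)
    res <- checkExhaustion(computeVo2max(tr, co$weight[i]), co$age[i])
    expect_true(res$exhausted)
    expect_gt(res$hrmax, 0.9 * (208 - 0.7 * co$age[i]))
    expect_gt(res$rer_final, 1.05)
  }
  flagged <- co[1, ]
  flagged$premature_termination <- TRUE
  tr <- simulateCpet(flagged, cpetSimConfig(), seed = 77)
  res <- checkExhaustion(computeVo2max(tr, flagged$weight), flagged$age)
  expect_false(res$exhausted)
})

test_that("noise-free CPET recovers the latent VO2max closely", {
  co <- quietCohort(4, seed = 51)
  for (i in seq_len(4)) {
    tr <- simulateCpet(co[i, ], noiseFreeCpet(), seed = i)
    res <- computeVo2max(tr, co$weight[i])
    expect_equal(res$vo2max_rel, co$true_vo2max_rel[i], tolerance = 0.01)
  }
})

test_that("CPET simulation is deterministic given the seed", {
  subj <- quietCohort(1, seed = 61)[1, ]
  expect_identical(simulateCpet(subj, cpetSimConfig(), seed = 8),
                   simulateCpet(subj, cpetSimConfig(), seed = 8))
})

test_that("generated features track latent fitness across a cohort", {
  co <- quietCohort(150, seed = 71)
  ft <- cohortFeatures(co, noiseFreeScg(restHrSd = 0))$features
  v <- ft$true_vo2max_rel
  expect_gt(cor(v, ft$dia_ptp), 0.9)
  expect_gt(cor(v, ft$sys_spec), 0.9)
  expect_gt(cor(v, ft$dia_morph), 0.9)
  expect_gt(cor(v, ft$rr_ms), 0.9)  # lower HR (longer RR) in fitter subjects
})
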