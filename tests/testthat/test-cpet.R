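# CPET processing: ramp profile, last-30-s extraction, exhaustion and
# exclusion rules.

test_that("ramp power reproduces the protocol timings", {
  cfg <- cpetSimConfig()
  expect_equal(rampPower(120, cfg), 50)
  expect_equal(rampPower(183.6, cfg), 51)   # first 1-W step after 3 min
  expect_equal(rampPower(360, cfg), 100)    # 50 W per 3 min equivalence
  expect_error(rampPower(-1, cfg), "non-negative")
  t <- seq(0, 1200, by = 0.37)
  expect_true(all(diff(rampPower(t, cfg)) >= 0))
})

test_that("VO2max extraction averages the final 30 s correctly", {
  t <- seq(0, 120, by = 2)
  constant <- data.frame(t = t, power = 100, vo2 = 2000, vco2 = 2100,
                         hr = 150)
  expect_equal(computeVo2max(constant, 80)$vo2max_abs, 2000)

  # linear 2000 -> 2600 over the last 30 s: time-weighted mean = midpoint
  vo2 <- ifelse(t < 90, 2000, 2000 + (t - 90) * 20)
  linear <- data.frame(t = t, power = 100, vo2 = vo2, vco2 = vo2, hr = 150)
  expect_equal(computeVo2max(linear, 80)$vo2max_abs, 2300)

  expect_equal(computeVo2max(constant, 76.5)$vo2max_rel, 2000 / 76.5)
  short <- constant[t <= 20, ]
  expect_error(computeVo2max(short, 80), "30 s")
})

test_that("breaths before the 30-s window never affect VO2max", {
  set.seed(5)
  t <- sort(runif(80, 0, 300))
  tr <- data.frame(t = t, power = rampPower(t, cpetSimConfig()),
                   vo2 = 1500 + 4 * t + rnorm(80, 0, 30),
                   vco2 = 1600 + 4 * t, hr = 100 + 0.2 * t)
  base <- computeVo2max(tr, 75)
  tweak <- tr
  early <- tweak$t < max(tweak$t) - 31
  tweak$vo2[early] <- tweak$vo2[early] + 500
  tweak$hr[early] <- tweak$hr[early] + 30
  after <- computeVo2max(tweak, 75)
  expect_equal(after$vo2max_abs, base$vo2max_abs)
  expect_equal(after$hrmax, base$hrmax)
})

test_that("exhaustion criteria apply the printed formulas strictly", {
  row <- data.frame(vo2max_abs = 2800, vo2max_rel = 37, hrmax = 160,
                    peak_power = 250, rer_final = 1.10,
                    hr_criterion_met = NA, rer_criterion_met = NA,
                    exhausted = NA)
  expect_true(checkExhaustion(row, 50)$exhausted)      # 160 > 155.7
  row$hrmax <- 150
  expect_false(checkExhaustion(row, 50)$exhausted)     # 150 < 155.7
  row$hrmax <- 160
  row$rer_final <- 1.05
  expect_false(checkExhaustion(row, 50)$rer_criterion_met)  # strict >
})

test_that("exclusion filter removes flagged subjects and conserves counts", {
  co <- generateCohort(cohortSpec(n = 107, nPremature = 11L, nBattery = 2L,
                                  seed = 4))
  co$exhausted <- !co$premature_termination
  out <- applyExclusions(co)
  expect_equal(nrow(out$included), 94L)
  expect_equal(unname(out$tally),
               c(11L, 2L))
  expect_equal(nrow(out$included) + sum(out$tally), nrow(co))

  # no flags -> no-op filter
  clean <- data.frame(exhausted = rep(TRUE, 5),
                      battery_failure = rep(FALSE, 5))
  expect_equal(nrow(applyExclusions(clean)$included), 5L)

  # everything flagged -> empty inclusion, full tally
  all_out <- data.frame(exhausted = c(FALSE, FALSE, TRUE),
                        battery_failure = c(FALSE, TRUE, TRUE))
  res <- applyExclusions(all_out)
  expect_equal(nrow(res$included), 0L)
  expect_equal(sum(res$tally), 3L)

  expect_error(applyExclusions(data.frame()), "non-empty")
})

test_that("exclusion conservation holds on random flag patterns", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(3:40, 1)
    df <- data.frame(exhausted = runif(n) > 0.2,
                     battery_failure = runif(n) < 0.15)
    out <- applyExclusions(df)
    expect_equal(nrow(out$included) + sum(out$tally), n)
  }
})
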