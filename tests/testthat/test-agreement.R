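# Method-comparison statistics.

test_that("perfect agreement and constant offsets behave exactly", {
  ref <- c(30, 35, 40, 45, 50)
  same <- agreementReport(pairedScores(1:5, ref, ref))
  expect_equal(same@bias, 0)
  expect_equal(same@mape, 0)
  expect_equal(same@see, 0)
  expect_equal(same@loa, c(0, 0))
  expect_equal(same@biasP, 1)

  off <- agreementReport(pairedScores(1:5, ref + 5, ref))
  expect_equal(off@bias, 5)
  expect_equal(off@loa, c(5, 5))   # zero-width band
  expect_equal(off@r, 1)
  expect_equal(off@see, 0, tolerance = 1e-12)
  expect_equal(off@biasP, 0)
})

test_that("missing pairs are dropped and zero references rejected", {
  p <- pairedScores(1:5, c(30, NA, 35, 40, 42), c(31, 32, 36, NA, 45))
  expect_equal(length(p@ids), 3L)
  expect_equal(p@nDropped, 2L)
  bad <- pairedScores(1:3, c(30, 35, 40), c(31, 0, 36))
  expect_error(agreementReport(bad), "MAPE undefined")
  expect_error(pairedScores(1:2, c(1, 2), c(1, 2)), "at least 3")
})

test_that("limits of agreement match the Gaussian closed form", {
  set.seed(42)
  ref <- rnorm(200, 37, 8.6)
  est <- ref + rnorm(200, 0, 4.87)
  rep <- agreementReport(pairedScores(seq_along(ref), est, ref))
  # expected band roughly bias +/- 1.96 * 4.87 = +/- 9.5
  expect_equal(rep@loa[2] - rep@bias, 9.5, tolerance = 0.15)
  expect_equal(rep@bias - rep@loa[1], 9.5, tolerance = 0.15)
  d <- est - ref
  inside <- mean(d > rep@loa[1] & d < rep@loa[2])
  expect_gt(inside, 0.90)
  expect_lt(inside, 1.00)
})

test_that("LoA width identity holds on arbitrary inputs", {
  set.seed(7)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    ref <- runif(n, 20, 60)
    est <- ref + rnorm(n, runif(1, -5, 5), runif(1, 0, 6))
    rep <- agreementReport(pairedScores(seq_len(n), est, ref))
    expect_equal(rep@loa[2] - rep@loa[1], 2 * 1.96 * sd(est - ref),
                 tolerance = 1e-9)
  }
})

test_that("SEE equals the n-2 residual SD of reference on estimate", {
  set.seed(3)
  ref <- rnorm(50, 37, 8)
  est <- ref + rnorm(50, 0, 5)
  rep <- agreementReport(pairedScores(1:50, est, ref))
  fit <- lm(ref ~ est)
  expect_equal(rep@see, sqrt(sum(residuals(fit)^2) / 48), tolerance = 1e-12)
})

test_that("absolute-agreement ICC matches hand-computable cases", {
  m <- matrix(rnorm(20), 10, 2)
  same <- iccAbsoluteAgreement(cbind(m[, 1], m[, 1]))
  expect_equal(same@value, 1)

  toy <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
  expect_equal(iccAbsoluteAgreement(toy)@value, iccOracleAov(toy),
               tolerance = 1e-12)

  # a large constant offset hurts absolute agreement but not consistency
  x <- rnorm(12, 40, 8)
  shifted <- cbind(x, x + 10)
  res <- iccAbsoluteAgreement(shifted)
  consistency <- (res@msr - res@mse) / (res@msr + (res@k - 1) * res@mse)
  expect_lt(res@value, consistency)
  expect_lt(res@value, 0.9)

  expect_error(iccAbsoluteAgreement(matrix(c(1, 2, NA, 4, 5, 6), 3, 2)),
               "missing")
  expect_error(iccAbsoluteAgreement(matrix(1:4, 2, 2)), "at least 3")
})

test_that("Steiger test has the stated symmetries", {
  none <- steigerTest(0.8, 0.8, 0.6, 93)
  expect_equal(none@z, 0)
  expect_equal(none@p, 1)

  ab <- steigerTest(0.832, 0.752, 0.7, 93)
  ba <- steigerTest(0.752, 0.832, 0.7, 93)
  expect_equal(ab@z, -ba@z)
  expect_equal(ab@p, ba@p)
  expect_gt(ab@z, 0)

  expect_error(steigerTest(1, 0.5, 0.3, 50), "degenerate")
  expect_error(steigerTest(0.8, 0.7, 0.6, 5), "at least 10")
})

test_that("paired MAPE comparison detects doubled errors", {
  set.seed(11)
  detected <- replicate(30, {
    ref <- rnorm(100, 37, 8)
    err <- rnorm(100, 0, 3)
    p1 <- pairedScores(1:100, ref + err, ref)
    p2 <- pairedScores(1:100, ref + 2 * err, ref)
    compareMape(p1, p2)$p.value < 0.05
  })
  expect_gte(mean(detected), 0.95)

  ref <- c(30, 35, 40)
  p <- pairedScores(1:3, ref + 1, ref)
  expect_equal(compareMape(p, p)$p.value, 1)
  q <- pairedScores(4:6, ref + 1, ref)
  expect_error(compareMape(p, q), "alignment error")
})

test_that("RMS difference matches direct arithmetic", {
  ref <- c(10, 10, 10)
  expect_equal(rmsDifference(pairedScores(1:3, ref, ref)), 0)
  expect_equal(rmsDifference(pairedScores(1:3, ref + c(3, 4, 0), ref)),
               sqrt(25 / 3))
  expect_equal(rmsDifference(pairedScores(1:3, ref + 2, ref)), 2)
})

test_that("MAPE t-interval keeps near-nominal coverage at n = 93", {
  set.seed(21)
  n <- 93
  mu <- log(10)
  sig <- 0.5
  trueMape <- exp(mu + sig^2 / 2)
  cover <- replicate(1000, {
    ref <- rnorm(n, 40, 5)
    ape <- rlnorm(n, mu, sig)                      # APE in percent
    est <- ref * (1 + sample(c(-1, 1), n, TRUE) * ape / 100)
    rep <- agreementReport(pairedScores(seq_len(n), est, ref))
    rep@mapeCI[1] <= trueMape && trueMape <= rep@mapeCI[2]
  })
  expect_equal(mean(cover), 0.95, tolerance = 0.032)
})

test_that("subgroup analysis partitions and flags small strata", {
  set.seed(31)
  n <- 40
  cohort <- data.frame(subject_id = as.character(1:n),
                       sex = rep(0:1, n / 2),
                       active_lifestyle = rep(c(TRUE, FALSE), each = n / 2),
                       bmi = runif(n, 20, 29),
                       age = runif(n, 30, 65))
  ref <- rnorm(n, 37, 8) + 6 * cohort$active_lifestyle
  est <- ref + rnorm(n, 0, 3)
  cohort$vo2max_rel_ref <- ref
  p <- pairedScores(cohort$subject_id, est, ref)

  one <- subgroupAnalysis(cohort, p,
                          subgroupSpec("All", "sex", breaks = c(-Inf, Inf),
                                       labels = "everyone"))
  whole <- agreementReport(p)
  expect_equal(one$bias, whole@bias)
  expect_equal(one$mape, whole@mape)
  expect_equal(one$n, whole@n)

  act <- subgroupAnalysis(cohort, p, defaultSubgroupSpecs()[[1]])
  expect_equal(act$stratum, c("sedentary", "active"))
  expect_false(any(act$insufficient))

  tiny <- data.frame(subject_id = as.character(1:3), bmi = c(24, 27, 31))
  pt <- pairedScores(tiny$subject_id, c(35, 36, 37), c(34, 35, 36))
  bmiSpec <- subgroupSpec("BMI", "bmi", breaks = c(-Inf, 25, 30, Inf),
                          labels = c("normal", "overweight", "obese"))
  res <- subgroupAnalysis(tiny, pt, bmiSpec)
  expect_equal(res$n, c(1L, 1L, 1L))
  expect_true(all(res$insufficient))
})

test_that("activity-stratified estimates reflect the generated effect", {
  set.seed(41)
  co <- quietCohort(80, seed = 41)
  est <- co$true_vo2max_rel + rnorm(80, 0, 3)
  ref <- co$true_vo2max_rel + rnorm(80, 0, 2)
  co$vo2max_rel_ref <- ref
  p <- pairedScores(co$subject_id, est, ref)
  tab <- subgroupAnalysis(co, p, defaultSubgroupSpecs()[[1]])
  mAct <- mean(est[co$active_lifestyle])
  mSed <- mean(est[!co$active_lifestyle])
  expect_gt(mAct, mSed)
  expect_equal(tab$n[tab$stratum == "active"], sum(co$active_lifestyle))
})
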