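# Synthetic cohort generator.

#' Generate a synthetic subject cohort
#'
#' Draws demographics from the distributions in `spec` and assigns each
#' subject a latent ground-truth relative VO2max from the linear model
#' `intercept + female*sex + age*years + active*lifestyle + N(0, sd)`,
#' truncated to (10, 90) mL/min/kg. A configurable number of subjects is
#' flagged for premature CPET termination and for device battery failure
#' (disjoint sets, chosen at random).
#'
#' @param spec a [CohortSpec-class]; its `seed` makes the draw deterministic.
#' @return A data.frame with one row per subject and columns `subject_id`,
#'   `sex` (0 = male, 1 = female), `age` (years), `height` (m), `weight`
#'   (kg), `bmi`, `active_lifestyle` (logical), `true_vo2max_rel`
#'   (mL/min/kg), `premature_termination`, `battery_failure` (logical).
#' @export
#' @examples
#' cohort <- generateCohort(cohortSpec(n = 20, nPremature = 2L,
#'                                     nBattery = 1L, seed = 7))
#' summary(cohort$true_vo2max_rel)
generateCohort <- function(spec) {
  stopifnot(methods::is(spec, "CohortSpec"))
  methods::validObject(spec)
  n <- spec@n
  withSeed(spec@seed, {
    sex <- as.integer(stats::runif(n) < spec@sexFemaleProb)
    age <- truncNorm(n, spec@ageMean, spec@ageSd, 18, 95)
    height <- truncNorm(n, spec@heightMean, spec@heightSd, 1.2, 2.2)
    weight <- truncNorm(n, spec@weightMean, spec@weightSd, 30, 200)
    active <- stats::runif(n) < spec@activeProb
    m <- spec@vo2maxModel
    vo2 <- m[["intercept"]] + m[["female"]] * sex + m[["age"]] * age +
      m[["active"]] * active + stats::rnorm(n, 0, m[["sd"]])
    vo2 <- pmin(pmax(vo2, 10 + 1e-6), 90 - 1e-6)
    flagged <- sample.int(n, spec@nPremature + spec@nBattery)
    premature <- logical(n)
    battery <- logical(n)
    if (spec@nPremature > 0L)
      premature[flagged[seq_len(spec@nPremature)]] <- TRUE
    if (spec@nBattery > 0L)
      battery[flagged[spec@nPremature + seq_len(spec@nBattery)]] <- TRUE
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n)),
      sex = sex, age = age, height = height, weight = weight,
      bmi = weight / height^2, active_lifestyle = active,
      true_vo2max_rel = as.numeric(vo2),
      premature_termination = premature, battery_failure = battery,
      stringsAsFactors = FALSE)
  })
}

# Truncated-normal draw by resampling out-of-range values.
truncNorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= lo | x >= hi)
  for (i in bad) {
    repeat {
      v <- stats::rnorm(1L, mean, sd)
      if (v > lo && v < hi) break
    }
    x[i] <- v
  }
  x
}
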