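# Method-comparison statistics: bias, MAPE, SEE, Pearson with Fisher-z CI,
# Bland-Altman limits of agreement, two-way absolute-agreement ICC, Steiger
# test for dependent correlations, RMS difference, paired MAPE comparison
# and subgroup stratification.

#' Construct aligned estimator/reference score pairs
#'
#' Pairs with a missing value on either side are dropped listwise and
#' counted, mirroring the per-estimator sample sizes a validation study
#' reports when individual measurements fail.
#'
#' @param ids subject identifiers (unique).
#' @param estimate estimator values (mL/min/kg).
#' @param reference reference CPET values (mL/min/kg).
#' @return A [PairedScores-class].
#' @export
#' @examples
#' pairedScores(letters[1:5], c(30, NA, 35, 40, 42), c(31, 32, 36, 39, 45))
pairedScores <- function(ids, estimate, reference) {
  stopifnot(length(ids) == length(estimate),
            length(ids) == length(reference))
  keep <- !(is.na(estimate) | is.na(reference))
  methods::new("PairedScores", ids = as.character(ids)[keep],
               estimate = as.numeric(estimate)[keep],
               reference = as.numeric(reference)[keep],
               nDropped = as.integer(sum(!keep)))
}

# Fisher-z confidence interval for a Pearson correlation.
fisherCI <- function(r, n, level = 0.95) {
  if (abs(r) >= 1 - 1e-12) return(c(r, r))
  z <- atanh(r)
  half <- stats::qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

# Mean with t-based CI; degenerate (zero-variance) samples collapse to a
# point interval with p = 1 when the mean is 0 and p = 0 otherwise.
tMeanCI <- function(x, level = 0.95) {
  m <- mean(x)
  if (length(x) < 2L || stats::sd(x) == 0)
    return(list(mean = m, ci = c(m, m),
                p = if (isTRUE(all.equal(m, 0))) 1 else 0))
  tt <- stats::t.test(x, conf.level = level)
  list(mean = m, ci = as.numeric(tt$conf.int), p = tt$p.value)
}

#' Full agreement report for one estimator against the reference
#'
#' Computes bias (mean of estimate minus reference) with paired-t 95% CI and
#' p-value; MAPE (mean of 100*|difference|/reference) with a t-based CI on
#' the per-subject absolute percentage errors; Pearson r with Fisher-z CI;
#' SEE (residual SD, divisor n-2, of the OLS regression of reference on
#' estimate); and Bland-Altman limits of agreement (bias +/- 1.96 * SD of
#' the differences).
#'
#' @param p a [PairedScores-class].
#' @return An [AgreementReport-class].
#' @export
#' @examples
#' set.seed(1)
#' ref <- rnorm(93, 37.2, 8.6)
#' est <- ref + rnorm(93, 0, 4.9)
#' agreementReport(pairedScores(seq_along(ref), est, ref))
agreementReport <- function(p) {
  stopifnot(methods::is(p, "PairedScores"))
  est <- p@estimate
  ref <- p@reference
  n <- length(est)
  if (any(ref == 0))
    stop("MAPE undefined: reference contains zero values", call. = FALSE)
  d <- est - ref
  bias <- tMeanCI(d)
  ape <- 100 * abs(d) / ref
  mape <- tMeanCI(ape)
  r <- if (stats::sd(est) == 0 || stats::sd(ref) == 0) NA_real_
       else stats::cor(est, ref)
  rCI <- if (is.na(r)) c(NA_real_, NA_real_) else fisherCI(r, n)
  see <- if (stats::sd(est) == 0) NA_real_
         else suppressWarnings(summary(stats::lm(ref ~ est))$sigma)
  sdD <- stats::sd(d)
  methods::new("AgreementReport", n = as.integer(n), bias = bias$mean,
               biasCI = bias$ci, biasP = bias$p, mape = mape$mean,
               mapeCI = mape$ci, r = r, rCI = rCI, see = see,
               loa = c(bias$mean - 1.96 * sdD, bias$mean + 1.96 * sdD))
}

# Flatten an AgreementReport into a one-row data.frame (reporting layer).
agreementRow <- function(rep) {
  data.frame(n = rep@n, bias = rep@bias, bias_lo = rep@biasCI[1L],
             bias_hi = rep@biasCI[2L], bias_p = rep@biasP, mape = rep@mape,
             mape_lo = rep@mapeCI[1L], mape_hi = rep@mapeCI[2L], r = rep@r,
             r_lo = rep@rCI[1L], r_hi = rep@rCI[2L], see = rep@see,
             loa_lower = rep@loa[1L], loa_upper = rep@loa[2L])
}

#' Two-way absolute-agreement intraclass correlation, single measurement
#'
#' ICC(A,1): `(MSR - MSE) / (MSR + (k-1)*MSE + (k/n)*(MSC - MSE))` from the
#' two-way crossed mean squares (rows = subjects, columns = repeated
#' measurements). This is the test-retest reliability variant that
#' penalizes systematic offsets between repeats.
#'
#' @param ratings numeric matrix, n subjects x k measurements, complete.
#' @return An [ICCResult-class].
#' @export
#' @examples
#' m <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' iccAbsoluteAgreement(m)
iccAbsoluteAgreement <- function(ratings) {
  x <- as.matrix(ratings)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 3L || k < 2L)
    stop("invalid ratings: need at least 3 subjects and 2 measurements",
         call. = FALSE)
  if (anyNA(x))
    stop("missing cells are not allowed (no imputation)", call. = FALSE)
  g <- mean(x)
  rm <- rowMeans(x)
  cm <- colMeans(x)
  msr <- k * sum((rm - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  resid <- x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  value <- if (denom == 0) 1 else (msr - mse) / denom
  methods::new("ICCResult", value = value, variant = "ICC(A,1)",
               msr = msr, msc = msc, mse = mse,
               n = as.integer(n), k = as.integer(k))
}

#' Steiger test for two dependent correlations sharing one variable
#'
#' Compares `r1 = cor(reference, estimatorA)` against
#' `r2 = cor(reference, estimatorB)` measured on the same n subjects, given
#' the inter-estimator correlation `r12`. Uses the Fisher-transformed
#' difference scaled by the Steiger (1980) covariance term evaluated at the
#' back-transformed mean correlation, with a two-sided normal p-value.
#'
#' @param r1,r2 the two dependent correlations, in (-1, 1).
#' @param r12 correlation between the two estimators, in (-1, 1).
#' @param n sample size (>= 10).
#' @return A [SteigerResult-class].
#' @export
#' @examples
#' steigerTest(0.832, 0.752, 0.70, 93)
steigerTest <- function(r1, r2, r12, n) {
  if (any(abs(c(r1, r2, r12)) >= 1))
    stop("degenerate input: correlations must lie strictly in (-1, 1)",
         call. = FALSE)
  if (n < 10L) stop("invalid n: need at least 10 subjects", call. = FALSE)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  rbar <- tanh((z1 + z2) / 2)
  psi <- r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)
  covz <- psi / (1 - rbar^2)^2
  denom <- 2 - 2 * covz
  if (denom <= 0)
    stop("degenerate input: implied covariance is not positive definite",
         call. = FALSE)
  z <- (z1 - z2) * sqrt((n - 3) / denom)
  methods::new("SteigerResult", z = z, p = 2 * stats::pnorm(-abs(z)),
               r1 = r1, r2 = r2, r12 = r12, n = as.integer(n))
}

#' Paired comparison of two estimators' absolute percentage errors
#'
#' Differences the per-subject absolute percentage errors of two estimators
#' on their common subjects and applies a paired t-test; this is the test
#' used to declare one MAPE significantly smaller than another.
#'
#' @param p1,p2 [PairedScores-class] objects sharing subjects.
#' @return A list with `t`, `p.value`, `n`, and `mean_ape_diff`
#'   (APE1 - APE2, percentage points).
#' @export
compareMape <- function(p1, p2) {
  common <- intersect(p1@ids, p2@ids)
  if (length(common) == 0L)
    stop("alignment error: the two estimators share no subjects",
         call. = FALSE)
  if (length(common) < 3L)
    stop("alignment error: fewer than 3 common subjects", call. = FALSE)
  i1 <- match(common, p1@ids)
  i2 <- match(common, p2@ids)
  ape1 <- 100 * abs(p1@estimate[i1] - p1@reference[i1]) / p1@reference[i1]
  ape2 <- 100 * abs(p2@estimate[i2] - p2@reference[i2]) / p2@reference[i2]
  d <- ape1 - ape2
  if (stats::sd(d) == 0) {
    return(list(t = 0, p.value = 1, n = length(d), mean_ape_diff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(t = as.numeric(tt$statistic), p.value = tt$p.value, n = length(d),
       mean_ape_diff = mean(d))
}

#' Root-mean-square difference between paired scores
#'
#' @param p a [PairedScores-class].
#' @return RMS of (estimate - reference) in mL/min/kg.
#' @export
#' @examples
#' p <- pairedScores(1:3, c(40, 41, 36), c(37, 37, 36))
#' rmsDifference(p)
rmsDifference <- function(p) {
  stopifnot(methods::is(p, "PairedScores"))
  sqrt(mean((p@estimate - p@reference)^2))
}

#' Define a subgroup stratifier
#'
#' @param name stratifier label (e.g. "BMI").
#' @param var column of the cohort data.frame to stratify on.
#' @param breaks optional numeric cut points (left-closed bins, so a break
#'   at 50 puts age 50 in the older group); omit for categorical columns.
#' @param labels optional bin or level labels.
#' @return A `subgroupSpec` list usable with [subgroupAnalysis()].
#' @export
subgroupSpec <- function(name, var, breaks = NULL, labels = NULL) {
  if (!is.null(breaks) && !is.null(labels) &&
      length(labels) != length(breaks) - 1L)
    stop("invalid spec: need one label per bin", call. = FALSE)
  structure(list(name = name, var = var, breaks = breaks, labels = labels),
            class = "subgroupSpec")
}

#' Default subgroup stratifiers of the validation study
#'
#' Sex; age below / at-or-above 50 years; active (>= 5 h exercise/week) vs
#' sedentary lifestyle; BMI < 25 / 25-29.9 / >= 30 kg/m^2; and reference
#' fitness < 30 / 30-44.9 / >= 45 mL/min/kg (requires a `vo2max_rel_ref`
#' column).
#'
#' @return List of [subgroupSpec()] objects.
#' @export
defaultSubgroupSpecs <- function() {
  list(
    subgroupSpec("Activity level", "active_lifestyle",
                 labels = c(`FALSE` = "sedentary", `TRUE` = "active")),
    subgroupSpec("Sex", "sex", labels = c(`0` = "male", `1` = "female")),
    subgroupSpec("Fitness level", "vo2max_rel_ref", breaks = c(-Inf, 30, 45, Inf),
                 labels = c("low (<30)", "moderate (30-44.9)", "high (>=45)")),
    subgroupSpec("BMI", "bmi", breaks = c(-Inf, 25, 30, Inf),
                 labels = c("normal (<25)", "overweight (25-29.9)",
                            "obese (>=30)")),
    subgroupSpec("Age", "age", breaks = c(-Inf, 50, Inf),
                 labels = c("<50 years", ">=50 years")))
}

# Assign each cohort row to a stratum under one subgroupSpec.
assignStrata <- function(cohort, spec) {
  v <- cohort[[spec$var]]
  if (is.null(v))
    stop(sprintf("stratifier column '%s' not found", spec$var), call. = FALSE)
  if (is.null(spec$breaks)) {
    s <- as.character(v)
    if (!is.null(spec$labels)) s <- unname(spec$labels[s])
    s
  } else {
    as.character(cut(v, breaks = spec$breaks, labels = spec$labels,
                     right = FALSE))
  }
}

#' Per-stratum agreement analysis
#'
#' Partitions the paired scores by one or more stratifiers and emits one
#' [agreementReport()] row per stratum. Strata with fewer than 3 pairs are
#' reported with `insufficient = TRUE` and NA statistics.
#'
#' @param cohort data.frame with `subject_id` plus the stratifier columns.
#' @param p a [PairedScores-class]; ids must appear in `cohort$subject_id`.
#' @param specs a [subgroupSpec()] or list of them
#'   (default [defaultSubgroupSpecs()]).
#' @return data.frame with one row per stratum: stratifier, stratum, n and
#'   the flattened agreement statistics.
#' @export
subgroupAnalysis <- function(cohort, p, specs = defaultSubgroupSpecs()) {
  stopifnot(methods::is(p, "PairedScores"))
  if (inherits(specs, "subgroupSpec")) specs <- list(specs)
  idx <- match(p@ids, cohort$subject_id)
  if (anyNA(idx))
    stop("alignment error: some paired ids are missing from the cohort",
         call. = FALSE)
  naRow <- agreementRow(methods::new(
    "AgreementReport", n = 3L, bias = 0, biasCI = c(0, 0), biasP = 1,
    mape = 0, mapeCI = c(0, 0), r = NA_real_, rCI = c(NA_real_, NA_real_),
    see = NA_real_, loa = c(0, 0)))
  naRow[] <- NA

  out <- lapply(specs, function(spec) {
    strata <- assignStrata(cohort, spec)[idx]
    levs <- if (!is.null(spec$labels)) unique(unname(spec$labels))
            else sort(unique(strata))
    rows <- lapply(levs, function(lv) {
      sel <- which(strata == lv)
      if (length(sel) < 3L) {
        row <- naRow
        row$n <- length(sel)
        cbind(data.frame(stratifier = spec$name, stratum = lv,
                         insufficient = TRUE), row)
      } else {
        sub <- pairedScores(p@ids[sel], p@estimate[sel], p@reference[sel])
        cbind(data.frame(stratifier = spec$name, stratum = lv,
                         insufficient = FALSE),
              agreementRow(agreementReport(sub)))
      }
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
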