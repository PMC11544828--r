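# VO2max estimation models: the linear SCG regression and the published
# non-exercise benchmark equations.

scgPredictors <- c("sex", "age", "weight", "height", "rr_ms", "dia_ptp",
                   "dia_morph", "sys_spec")

#' Fit the linear SCG VO2max regression
#'
#' Ordinary least squares of relative VO2max (mL/min/kg) on sex (0 = male,
#' 1 = female), age (years), weight (kg), height (m) and the four SCG
#' features (RR in ms, diastolic peak-to-peak in m/s^2, diastolic morphology
#' score, systolic spectrum score). Plain OLS is used deliberately: the
#' published model form is linear, and the proprietary training procedure
#' behind the commercial device is not reproduced here.
#'
#' @param data data.frame with the predictor columns above plus the response
#'   column `vo2max_rel`; at least 10 complete rows.
#' @return A [ScgVo2Model-class].
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(sex = rbinom(40, 1, .5), age = rnorm(40, 48, 9),
#'                 weight = rnorm(40, 76, 14), height = rnorm(40, 1.77, .08),
#'                 rr_ms = rnorm(40, 1000, 120), dia_ptp = rnorm(40, .7, .1),
#'                 dia_morph = rnorm(40), sys_spec = rnorm(40))
#' d$vo2max_rel <- 50 - 5 * d$sex - 0.3 * d$age + 10 * d$dia_ptp + rnorm(40)
#' fitScgVo2Model(d)
fitScgVo2Model <- function(data) {
  need <- c(scgPredictors, "vo2max_rel")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  data <- data[, need]
  if (anyNA(data))
    stop("missing values in predictors or response are not allowed",
         call. = FALSE)
  if (nrow(data) < 10L)
    stop("insufficient data: need at least 10 complete rows", call. = FALSE)

  X <- cbind(intercept = 1, as.matrix(data[, scgPredictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design: column(s) ", paste(dropped, collapse = ", "),
         " are linearly dependent", call. = FALSE)
  }
  fit <- stats::lm(stats::reformulate(scgPredictors, "vo2max_rel"),
                   data = data)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a perfect-fit warning
  co <- stats::coef(fit)
  names(co)[1L] <- "intercept"
  se <- sm$coefficients[, "Std. Error"]
  names(se) <- names(co)
  methods::new("ScgVo2Model", coefficients = co, se = se,
               fitN = nrow(data), residualSd = sm$sigma)
}

#' @describeIn fitScgVo2Model predict relative VO2max for new rows.
#' @param object a fitted `ScgVo2Model`.
#' @param newdata data.frame with the eight predictor columns.
#' @export
setMethod("predictVo2", "ScgVo2Model", function(object, newdata) {
  miss <- setdiff(scgPredictors, names(newdata))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  X <- cbind(1, as.matrix(newdata[, scgPredictors]))
  as.numeric(X %*% object@coefficients)
})

#' FRIENDS non-exercise VO2max equation
#'
#' `VO2max = 79.9 - 0.39*age - 13.7*sex - 0.127*weight_lbs` with sex coded
#' 0 = men, 1 = women. Weight is supplied in kilograms and converted
#' internally (x 2.20462). Because the equation is linear, evaluating it at
#' cohort means equals the cohort mean of per-subject evaluations, so
#' published cohort-level predictions are exactly recomputable from summary
#' statistics. Fractional `sexCode` values (e.g. a cohort female fraction)
#' are therefore allowed.
#'
#' @param age years (>= 0).
#' @param sexCode 0 = male, 1 = female; fractions allowed for cohort means.
#' @param weightKg body weight in kg (>= 0).
#' @return VO2max estimate in mL/min/kg (unrounded).
#' @export
#' @examples
#' round(predictFriends(48.2, 0.521, 76.5), 1)  # 32.5
predictFriends <- function(age, sexCode, weightKg) {
  if (any(age < 0) || any(sexCode < 0) || any(weightKg < 0))
    stop("invalid input: age, sexCode and weightKg must be non-negative",
         call. = FALSE)
  79.9 - 0.39 * age - 13.7 * sexCode - 0.127 * (weightKg * 2.20462)
}

#' ACSM peak-power VO2max equation
#'
#' `VO2max = 10.8 * peakPower / weight + 7` (mL/min/kg).
#'
#' @param peakPower peak power output (W).
#' @param weightKg body weight (kg, > 0).
#' @return VO2max estimate in mL/min/kg.
#' @export
#' @examples
#' predictAcsm(100, 100)  # 17.8
predictAcsm <- function(peakPower, weightKg) {
  if (any(weightKg <= 0))
    stop("invalid input: weightKg must be positive", call. = FALSE)
  10.8 * peakPower / weightKg + 7
}

#' Tanaka age-predicted maximal heart rate
#'
#' `HRmax = 208 - 0.7 * age` (BPM).
#'
#' @param age years.
#' @return Predicted maximal heart rate (BPM).
#' @export
#' @examples
#' tanakaHrMax(40)  # 180
tanakaHrMax <- function(age) 208 - 0.7 * age
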