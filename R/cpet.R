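# CPET processing: ramp power profile, last-30-s VO2max/HRmax extraction,
# exhaustion criteria and cohort exclusion rules.

#' Cycling power of the ramp protocol at time t
#'
#' 3 min (`baseDuration`) at `basePower` = 50 W, then `rampStep` = 1 W every
#' `rampInterval` = 3.6 s, applied stepwise in whole increments. A 1e-6
#' relative epsilon is added before the floor so that step-boundary times
#' (e.g. t = 183.6 s -> 51 W) land on the new step despite floating-point
#' representation of the 3.6-s interval.
#'
#' @param t numeric vector of times since exercise onset (s); must be >= 0.
#' @param cfg a [CPETSimConfig-class].
#' @return Numeric vector of power values (W), non-decreasing in `t`.
#' @export
#' @examples
#' rampPower(c(120, 183.6, 360), cpetSimConfig())  # 50, 51, 100
rampPower <- function(t, cfg = cpetSimConfig()) {
  if (any(t < 0)) stop("invalid 't': times must be non-negative", call. = FALSE)
  ramp <- pmax(0, t - cfg@baseDuration)
  cfg@basePower + cfg@rampStep * floor(ramp / cfg@rampInterval + 1e-6)
}

#' Extract VO2max, HRmax and peak power from a breath-by-breath trace
#'
#' VO2max and HRmax are the time-weighted (trapezoidal) means of VO2 and HR
#' over the final 30 s of loaded exercise, with the window's left edge
#' obtained by linear interpolation; the final respiratory exchange ratio is
#' the time-weighted mean of VCO2/VO2 over the same window. Peak power is
#' the maximum recorded load. The 50-W cool-down is assumed to have been
#' trimmed upstream: the trace must end at the termination of loaded
#' exercise.
#'
#' @param trace data.frame with columns `t` (s, strictly increasing),
#'   `power` (W), `vo2` (mL/min), `vco2` (mL/min), `hr` (BPM).
#' @param weight subject body weight (kg).
#' @return One-row data.frame: `vo2max_abs` (mL/min), `vo2max_rel`
#'   (mL/min/kg), `hrmax` (BPM), `peak_power` (W), `rer_final`, plus the
#'   (not yet evaluated) criteria columns filled by [checkExhaustion()].
#' @export
#' @examples
#' tr <- data.frame(t = seq(0, 60, 2), power = 100, vo2 = 2000,
#'                  vco2 = 2200, hr = 150)
#' computeVo2max(tr, weight = 80)
computeVo2max <- function(trace, weight) {
  stopifnot(all(c("t", "power", "vo2", "vco2", "hr") %in% names(trace)))
  if (any(diff(trace$t) <= 0))
    stop("invalid trace: times must be strictly increasing", call. = FALSE)
  tEnd <- trace$t[nrow(trace)]
  if (tEnd - trace$t[1L] < 30)
    stop("insufficient data: trace must span at least 30 s", call. = FALSE)
  t0 <- tEnd - 30
  winMean <- function(y) {
    keep <- trace$t >= t0
    ti <- trace$t[keep]
    yi <- y[keep]
    if (ti[1L] > t0) {  # interpolate the window's left edge
      y0 <- stats::approx(trace$t, y, xout = t0)$y
      ti <- c(t0, ti)
      yi <- c(y0, yi)
    }
    trapzMean(ti, yi)
  }
  vo2maxAbs <- winMean(trace$vo2)
  data.frame(
    vo2max_abs = vo2maxAbs,
    vo2max_rel = vo2maxAbs / weight,
    hrmax = winMean(trace$hr),
    peak_power = max(trace$power),
    rer_final = winMean(trace$vco2 / trace$vo2),
    hr_criterion_met = NA, rer_criterion_met = NA, exhausted = NA)
}

#' Apply the exhaustion criteria to a CPET result
#'
#' Exhaustion requires (A) last-30-s mean heart rate strictly above 90% of
#' the Tanaka age-predicted maximum (208 - 0.7 * age) and (B) last-30-s mean
#' respiratory exchange ratio strictly above 1.05.
#'
#' @param result one or more rows as returned by [computeVo2max()].
#' @param age subject age(s) in years, recycled against rows of `result`.
#' @return `result` with `hr_criterion_met`, `rer_criterion_met` and
#'   `exhausted` filled in.
#' @export
#' @examples
#' r <- data.frame(vo2max_abs = 2800, vo2max_rel = 37, hrmax = 160,
#'                 peak_power = 250, rer_final = 1.10,
#'                 hr_criterion_met = NA, rer_criterion_met = NA,
#'                 exhausted = NA)
#' checkExhaustion(r, age = 50)$exhausted  # TRUE: 160 > 0.9 * 173
checkExhaustion <- function(result, age) {
  result$hr_criterion_met <- result$hrmax > 0.9 * tanakaHrMax(age)
  result$rer_criterion_met <- result$rer_final > 1.05
  result$exhausted <- result$hr_criterion_met & result$rer_criterion_met
  result
}

#' Apply the study exclusion rules to a cohort
#'
#' Subjects failing the exhaustion criteria are excluded for premature
#' termination of spiroergometry; of the remainder, subjects whose device
#' battery failed are excluded for missing SCG recordings. The tally always
#' satisfies `nrow(included) + sum(tally) == nrow(cohort)`.
#'
#' @param cohort data.frame with at least columns `exhausted` (logical) and
#'   `battery_failure` (logical).
#' @return A list with `included` (the retained rows) and `tally` (named
#'   integer vector of exclusion counts per reason).
#' @export
#' @examples
#' df <- data.frame(exhausted = c(TRUE, FALSE, TRUE),
#'                  battery_failure = c(FALSE, FALSE, TRUE))
#' applyExclusions(df)$tally
applyExclusions <- function(cohort) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L)
    stop("invalid cohort: must be a non-empty data.frame", call. = FALSE)
  stopifnot(all(c("exhausted", "battery_failure") %in% names(cohort)))
  premature <- !cohort$exhausted
  battery <- cohort$battery_failure & !premature
  keep <- !premature & !battery
  list(included = cohort[keep, , drop = FALSE],
       tally = c(premature_termination = sum(premature),
                 battery_failure = sum(battery)))
}
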