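# Synthetic breath-by-breath CPET generator.

#' Simulate a ramp-protocol cardiopulmonary exercise test
#'
#' Produces breath samples at quasi-regular intervals. Power follows
#' [rampPower()]; oxygen uptake follows first-order kinetics toward a
#' power-proportional target capped at the subject's true absolute VO2max
#' (`true_vo2max_rel * weight`); heart rate rises linearly with the uptake
#' fraction toward the Tanaka age-predicted maximum; the respiratory
#' exchange ratio rises quadratically with the uptake fraction and crosses
#' 1.05 at `rerCrossingFrac` of full effort. Subjects exercise until the
#' uptake plateaus and then 35 s more, so that the last-30-s window meets
#' both exhaustion criteria. Subjects flagged with premature termination
#' have their effort ceiling reduced to `prematureFrac` of the true
#' maximum: uptake, heart rate and RER all plateau below the exhaustion
#' thresholds, so both criteria fail for any subject.
#'
#' @param subject one cohort row (see [generateCohort()]): needs
#'   `true_vo2max_rel`, `weight`, `age` and `premature_termination`.
#' @param cfg a [CPETSimConfig-class].
#' @param seed integer seed.
#' @return data.frame of breath samples with columns `t` (s), `power` (W),
#'   `vo2` (mL/min), `vco2` (mL/min), `hr` (BPM).
#' @export
#' @examples
#' subj <- generateCohort(cohortSpec(n = 1, nPremature = 0L,
#'                                   nBattery = 0L, seed = 5))[1, ]
#' tr <- simulateCpet(subj, cpetSimConfig(), seed = 2)
#' computeVo2max(tr, subj$weight)$vo2max_rel
simulateCpet <- function(subject, cfg = cpetSimConfig(), seed = 1L) {
  methods::validObject(cfg)
  cap <- subject$true_vo2max_rel * subject$weight
  hrMax <- tanakaHrMax(subject$age)
  premature <- isTRUE(subject$premature_termination)
  effCap <- if (premature) cfg@prematureFrac * cap else cap
  rerMax <- cfg@rerRest + (1.05 - cfg@rerRest) / cfg@rerCrossingFrac^2

  withSeed(seed, {
    t <- 0
    v <- cfg@vo2Rest
    rows <- vector("list", 2048L)
    i <- 0L
    plateauAt <- NA_real_
    repeat {
      dt <- max(0.5, stats::rnorm(1L, cfg@breathIntervalMean,
                                  cfg@breathIntervalSd))
      t <- t + dt
      p <- rampPower(t, cfg)
      target <- min(cfg@vo2Rest + cfg@vo2Gain * p, effCap)
      v <- v + (target - v) * (1 - exp(-dt / cfg@vo2TimeConstant))
      frac <- v / cap
      vo2Obs <- max(1, v + stats::rnorm(1L, 0, cfg@vo2NoiseSd))
      rer <- cfg@rerRest + (rerMax - cfg@rerRest) * frac^2
      hr <- cfg@hrRest + (hrMax - cfg@hrRest) * frac +
        stats::rnorm(1L, 0, cfg@hrNoiseSd)
      i <- i + 1L
      if (i > length(rows)) rows <- c(rows, vector("list", length(rows)))
      rows[[i]] <- c(t, p, vo2Obs, rer * vo2Obs, hr)
      if (is.na(plateauAt) && v >= 0.995 * effCap) plateauAt <- t
      if (!is.na(plateauAt) && t >= plateauAt + 35) break
      if (t > 3600) break  # safety stop
    }
    out <- as.data.frame(do.call(rbind, rows[seq_len(i)]))
    names(out) <- c("t", "power", "vo2", "vco2", "hr")
    out
  })
}
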