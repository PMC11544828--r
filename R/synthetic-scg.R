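# Synthetic SCG recording generator.
#
# Beat model: each heartbeat is a systolic Gabor burst (Gaussian-windowed
# cosine) centered on the fiducial, plus a diastolic burst placed at a fixed
# fraction of the nominal RR interval. The diastolic shape interpolates
# between a low-frequency and a high-frequency template; the blend parameter
# and the diastolic peak-to-peak amplitude rise with the subject's latent
# fitness, the systolic center frequency rises with fitness, and resting
# heart rate falls with fitness. Burst centers are snapped to the sample
# grid so that, with jitter and noise disabled, every beat is sample-wise
# identical — the analytic degeneracies the test suite relies on.

# Gaussian-windowed cosine on a time grid centered at 0.
gaborBurst <- function(tgrid, sigma, freq) {
  exp(-tgrid^2 / (2 * sigma^2)) * cos(2 * pi * freq * tgrid)
}

# Diastolic template blend, normalized to unit peak-to-peak on the grid.
# m = 0 gives the low-frequency template, m = 1 the high-frequency one.
diaTemplate <- function(tgrid, sigma, m) {
  shape <- (1 - m) * gaborBurst(tgrid, sigma, 6) +
    m * gaborBurst(tgrid, sigma, 10)
  shape / (max(shape) - min(shape))
}

# Systolic template, normalized to unit peak-to-peak.
sysTemplate <- function(tgrid, sigma, freq) {
  shape <- gaborBurst(tgrid, sigma, freq)
  shape / (max(shape) - min(shape))
}

#' Simulate a seismocardiography recording
#'
#' Generates a `duration * fs`-sample sternal acceleration trace for one
#' subject. Beats are placed at intervals of 60/HR s with Gaussian jitter;
#' the subject's heart rate combines a fitness-dependent mean, a stable
#' subject-level offset (reproducible across recordings of the same subject)
#' and within-recording noise. The `post_exercise` condition uses the
#' elevated heart-rate distribution and attenuates the diastolic amplitude.
#' True fiducial times (systolic-complex centers) are stored in the result,
#' alongside the generator's ground-truth feature values in `meta`.
#'
#' @param subject one cohort row (see [generateCohort()]) or any list with
#'   `subject_id` and `true_vo2max_rel`.
#' @param condition `"rest"` or `"post_exercise"`.
#' @param cfg an [SCGSimConfig-class].
#' @param seed integer seed for the recording-level randomness.
#' @return An [SCGRecording-class].
#' @export
#' @examples
#' subj <- generateCohort(cohortSpec(n = 1, nPremature = 0L,
#'                                   nBattery = 0L, seed = 3))[1, ]
#' rec <- simulateScg(subj, "rest", scgSimConfig(), seed = 11)
#' rec
simulateScg <- function(subject, condition = c("rest", "post_exercise"),
                        cfg = scgSimConfig(), seed = 1L) {
  condition <- match.arg(condition)
  methods::validObject(cfg)
  vo2 <- subject$true_vo2max_rel
  stopifnot(is.numeric(vo2), length(vo2) == 1L)

  sysFreq <- cfg@sysCenterFreqBase + cfg@sysFreqSlope * vo2
  if (sysFreq <= 0 || sysFreq > 0.45 * cfg@fs)
    stop(sprintf(
      "configuration error: systolic center frequency %.1f Hz is not representable at fs = %g Hz",
      sysFreq, cfg@fs), call. = FALSE)

  diaAmp <- cfg@diaAmpBase + cfg@diaAmpSlope * vo2
  if (diaAmp <= 0)
    stop("configuration error: diastolic amplitude is not positive",
         call. = FALSE)
  if (condition == "post_exercise") diaAmp <- diaAmp * cfg@postDiaAttenuation
  morph <- stats::plogis(cfg@diaMorphSlope * (vo2 - 37.2))

  hrMean <- if (condition == "rest") cfg@restHrMean else cfg@postExHrMean
  hrSd <- if (condition == "rest") cfg@restHrSd else cfg@postExHrSd
  zSubj <- subjectNormal(subject$subject_id, "hr")

  withSeed(seed, {
    hr <- hrMean - cfg@hrVo2Slope * (vo2 - 37.2) + zSubj * hrSd +
      stats::rnorm(1L, 0, cfg@hrNoiseSd)
    hr <- min(max(hr, 35), 140)
    rrNominal <- 60 / hr
    dt <- 1 / cfg@fs
    nSamp <- round(cfg@duration * cfg@fs)

    # beat placement, snapped to the sample grid
    fid <- numeric(0)
    t <- 0.5
    while (t + 0.9 * rrNominal <= cfg@duration) {
      fid <- c(fid, round(t * cfg@fs) / cfg@fs)
      t <- t + max(0.3, rrNominal + stats::rnorm(1L, 0, cfg@jitterSd))
    }
    if (length(fid) < 2L)
      stop("configuration error: recording too short for the beat rate",
           call. = FALSE)

    # per-beat waveform on offset grids (identical for every beat)
    sysOff <- ceiling(4 * cfg@sysSigma * cfg@fs)
    sysIdx <- (-sysOff):sysOff
    sysShape <- cfg@sysAmp * sysTemplate(sysIdx * dt, cfg@sysSigma, sysFreq)
    diaDelay <- round(cfg@diaPosFrac * rrNominal * cfg@fs)
    diaOff <- ceiling(3.5 * cfg@diaSigma * cfg@fs)
    diaIdx <- (-diaOff):diaOff
    diaShape <- diaAmp * diaTemplate(diaIdx * dt, cfg@diaSigma, morph)

    x <- numeric(nSamp)
    fidSamp <- round(fid * cfg@fs)
    for (k in fidSamp) {
      i <- k + sysIdx + 1L
      ok <- i >= 1L & i <= nSamp
      x[i[ok]] <- x[i[ok]] + sysShape[ok]
      j <- k + diaDelay + diaIdx + 1L
      ok <- j >= 1L & j <= nSamp
      x[j[ok]] <- x[j[ok]] + diaShape[ok]
    }
    if (cfg@noiseSd > 0) x <- x + stats::rnorm(nSamp, 0, cfg@noiseSd)

    methods::new("SCGRecording", samples = x, fs = cfg@fs, fiducials = fid,
                 condition = condition,
                 meta = list(subject_id = subject$subject_id,
                             true_vo2max_rel = vo2, hr = hr,
                             rr_nominal = rrNominal, sys_freq = sysFreq,
                             dia_ptp = diaAmp, dia_morph = morph))
  })
}
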