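# Configuration objects for the three generators and the study pipeline.
# Validity checks report the offending field by name.

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Defaults reproduce the recruited study population: 107 subjects, 52.1%
#' female, age 48.2 (8.7) y, height 1.77 (0.08) m, weight 76.5 (13.9) kg,
#' half with an active lifestyle (>= 5 h exercise/week), 11 subjects flagged
#' for premature CPET termination and 2 for device battery failure. The
#' latent ground-truth fitness follows
#' `vo2 = a0 + a1*female + a2*age + a3*active + N(0, sd)` with defaults
#' calibrated so the cohort mean/SD is close to 37.2 (8.6) mL/min/kg and the
#' active-sedentary gap close to 10 mL/min/kg.
#'
#' @slot n integer, cohort size.
#' @slot sexFemaleProb numeric in \[0,1\].
#' @slot ageMean,ageSd numeric, years.
#' @slot heightMean,heightSd numeric, metres.
#' @slot weightMean,weightSd numeric, kg.
#' @slot activeProb numeric in \[0,1\].
#' @slot vo2maxModel named numeric: intercept, female, age, active, sd.
#' @slot nPremature,nBattery integer, flagged subject counts.
#' @slot seed integer.
#' @export
setClass("CohortSpec",
  representation(n = "integer", sexFemaleProb = "numeric",
                 ageMean = "numeric", ageSd = "numeric",
                 heightMean = "numeric", heightSd = "numeric",
                 weightMean = "numeric", weightSd = "numeric",
                 activeProb = "numeric", vo2maxModel = "numeric",
                 nPremature = "integer", nBattery = "integer",
                 seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(object@n >= 1L, "n: must be >= 1")
  chk(object@sexFemaleProb >= 0 && object@sexFemaleProb <= 1,
      "sexFemaleProb: must lie in [0, 1]")
  chk(object@activeProb >= 0 && object@activeProb <= 1,
      "activeProb: must lie in [0, 1]")
  chk(object@ageSd >= 0, "ageSd: must be >= 0")
  chk(object@heightSd >= 0, "heightSd: must be >= 0")
  chk(object@weightSd >= 0, "weightSd: must be >= 0")
  chk(object@ageMean > 0, "ageMean: must be > 0")
  chk(object@heightMean > 1.2 && object@heightMean < 2.2,
      "heightMean: must lie in (1.2, 2.2)")
  chk(object@weightMean > 30, "weightMean: must be > 30")
  chk(all(c("intercept", "female", "age", "active", "sd") %in%
            names(object@vo2maxModel)),
      "vo2maxModel: needs named entries intercept, female, age, active, sd")
  chk(is.na(object@vo2maxModel["sd"]) || object@vo2maxModel["sd"] >= 0,
      "vo2maxModel: sd must be >= 0")
  chk(object@nPremature >= 0L && object@nBattery >= 0L &&
        object@nPremature + object@nBattery <= object@n,
      "nPremature/nBattery: flagged count cannot exceed n")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortSpec-class
#' @param n,sexFemaleProb,ageMean,ageSd,heightMean,heightSd,weightMean,weightSd
#'   see slots.
#' @param activeProb,vo2maxModel,nPremature,nBattery,seed see slots.
#' @return A validated `CohortSpec`.
#' @export
#' @examples
#' cohortSpec(n = 20, seed = 1)
cohortSpec <- function(n = 107L, sexFemaleProb = 0.521,
                       ageMean = 48.2, ageSd = 8.7,
                       heightMean = 1.77, heightSd = 0.08,
                       weightMean = 76.5, weightSd = 13.9,
                       activeProb = 0.5,
                       vo2maxModel = c(intercept = 52.717, female = -7,
                                       age = -0.35, active = 10, sd = 5.2),
                       nPremature = 11L, nBattery = 2L, seed = 1L) {
  methods::new("CohortSpec", n = as.integer(n), sexFemaleProb = sexFemaleProb,
               ageMean = ageMean, ageSd = ageSd, heightMean = heightMean,
               heightSd = heightSd, weightMean = weightMean,
               weightSd = weightSd, activeProb = activeProb,
               vo2maxModel = vo2maxModel, nPremature = as.integer(nPremature),
               nBattery = as.integer(nBattery), seed = as.integer(seed))
}

#' SCGSimConfig: parameters of the SCG recording simulator
#'
#' Each heartbeat is the sum of a systolic Gabor burst (Gaussian-windowed
#' cosine) whose center frequency rises with fitness, and a diastolic burst
#' whose peak-to-peak amplitude rises with fitness and whose shape
#' interpolates between a low- and a high-frequency template. Beats are
#' placed at intervals of 60/HR seconds with Gaussian jitter; white Gaussian
#' measurement noise is added. The post-exercise condition shifts the heart
#' rate distribution upward (Table-1-style 82 vs 60 BPM) and attenuates the
#' diastolic amplitude.
#'
#' @slot fs numeric, sampling rate Hz (default 250).
#' @slot duration numeric, s (default 42).
#' @slot sysAmp numeric, systolic burst peak-to-peak (m/s^2).
#' @slot sysCenterFreqBase numeric, Hz at VO2max = 0.
#' @slot sysFreqSlope numeric, Hz per (mL/min/kg).
#' @slot sysSigma numeric, systolic Gaussian envelope SD (s).
#' @slot diaAmpBase numeric, diastolic peak-to-peak at VO2max = 0 (m/s^2).
#' @slot diaAmpSlope numeric, per (mL/min/kg).
#' @slot diaMorphSlope numeric, logistic slope of the template-interpolation
#'   parameter per (mL/min/kg).
#' @slot diaSigma numeric, diastolic envelope SD (s).
#' @slot diaPosFrac numeric, diastolic burst center as fraction of nominal RR.
#' @slot restHrMean,restHrSd numeric, BPM (between-subject).
#' @slot postExHrMean,postExHrSd numeric, BPM (between-subject).
#' @slot hrVo2Slope numeric, BPM decrease per (mL/min/kg) above 37.2.
#' @slot hrNoiseSd numeric, BPM within-recording HR noise.
#' @slot postDiaAttenuation numeric, multiplier on diastolic amplitude after
#'   exercise.
#' @slot noiseSd numeric, additive white noise SD (m/s^2).
#' @slot jitterSd numeric, beat-interval jitter SD (s).
#' @export
setClass("SCGSimConfig",
  representation(fs = "numeric", duration = "numeric", sysAmp = "numeric",
                 sysCenterFreqBase = "numeric", sysFreqSlope = "numeric",
                 sysSigma = "numeric", diaAmpBase = "numeric",
                 diaAmpSlope = "numeric", diaMorphSlope = "numeric",
                 diaSigma = "numeric", diaPosFrac = "numeric",
                 restHrMean = "numeric", restHrSd = "numeric",
                 postExHrMean = "numeric", postExHrSd = "numeric",
                 hrVo2Slope = "numeric", hrNoiseSd = "numeric",
                 postDiaAttenuation = "numeric", noiseSd = "numeric",
                 jitterSd = "numeric"))

setValidity("SCGSimConfig", function(object) {
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(object@fs >= 100, "fs: must be >= 100 Hz")
  chk(object@duration > 0, "duration: must be > 0")
  chk(object@noiseSd >= 0, "noiseSd: must be >= 0")
  chk(object@jitterSd >= 0, "jitterSd: must be >= 0")
  chk(object@restHrSd >= 0, "restHrSd: must be >= 0")
  chk(object@postExHrSd >= 0, "postExHrSd: must be >= 0")
  chk(object@hrNoiseSd >= 0, "hrNoiseSd: must be >= 0")
  chk(object@sysSigma > 0, "sysSigma: must be > 0")
  chk(object@diaSigma > 0, "diaSigma: must be > 0")
  chk(object@diaPosFrac > 0 && object@diaPosFrac < 1,
      "diaPosFrac: must lie in (0, 1)")
  chk(object@postDiaAttenuation > 0 && object@postDiaAttenuation <= 1,
      "postDiaAttenuation: must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SCGSimConfig-class
#' @param fs,duration,sysAmp,sysCenterFreqBase,sysFreqSlope,sysSigma see slots.
#' @param diaAmpBase,diaAmpSlope,diaMorphSlope,diaSigma,diaPosFrac see slots.
#' @param restHrMean,restHrSd,postExHrMean,postExHrSd,hrVo2Slope see slots.
#' @param hrNoiseSd,postDiaAttenuation,noiseSd,jitterSd see slots.
#' @return A validated `SCGSimConfig`.
#' @export
#' @examples
#' scgSimConfig(noiseSd = 0, jitterSd = 0)
scgSimConfig <- function(fs = 250, duration = 42, sysAmp = 1.0,
                         sysCenterFreqBase = 15, sysFreqSlope = 0.2,
                         sysSigma = 0.02, diaAmpBase = 0.3,
                         diaAmpSlope = 0.01, diaMorphSlope = 0.05,
                         diaSigma = 0.05, diaPosFrac = 0.65,
                         restHrMean = 60.1, restHrSd = 8,
                         postExHrMean = 82.0, postExHrSd = 9.5,
                         hrVo2Slope = 0.5, hrNoiseSd = 1.5,
                         postDiaAttenuation = 0.85,
                         noiseSd = 0.05, jitterSd = 0.02) {
  methods::new("SCGSimConfig", fs = fs, duration = duration, sysAmp = sysAmp,
               sysCenterFreqBase = sysCenterFreqBase,
               sysFreqSlope = sysFreqSlope, sysSigma = sysSigma,
               diaAmpBase = diaAmpBase, diaAmpSlope = diaAmpSlope,
               diaMorphSlope = diaMorphSlope, diaSigma = diaSigma,
               diaPosFrac = diaPosFrac, restHrMean = restHrMean,
               restHrSd = restHrSd, postExHrMean = postExHrMean,
               postExHrSd = postExHrSd, hrVo2Slope = hrVo2Slope,
               hrNoiseSd = hrNoiseSd, postDiaAttenuation = postDiaAttenuation,
               noiseSd = noiseSd, jitterSd = jitterSd)
}

#' CPETSimConfig: parameters of the ramp-protocol CPET simulator
#'
#' Emulates a cycle-ergometer ramp test: 3 min at 50 W, then +1 W every
#' 3.6 s. Oxygen uptake follows first-order kinetics toward a
#' power-proportional target capped at the subject's true absolute VO2max;
#' heart rate rises toward the Tanaka age-predicted maximum; the respiratory
#' exchange ratio crosses 1.05 at a configurable fraction of the attainable
#' effort. The trace terminates ~35 s after the oxygen-uptake plateau so the
#' last-30-s window satisfies both exhaustion criteria, or earlier for
#' subjects flagged with premature termination.
#'
#' @slot basePower numeric, W (default 50).
#' @slot baseDuration numeric, s (default 180).
#' @slot rampStep numeric, W per increment (default 1).
#' @slot rampInterval numeric, s per increment (default 3.6).
#' @slot breathIntervalMean,breathIntervalSd numeric, s.
#' @slot vo2Rest numeric, resting oxygen uptake mL/min.
#' @slot vo2Gain numeric, mL/min per W (default 10.8, ACSM-consistent).
#' @slot vo2TimeConstant numeric, s.
#' @slot vo2NoiseSd numeric, mL/min breath-level noise.
#' @slot rerRest numeric, RER at rest.
#' @slot rerCrossingFrac numeric, fraction of peak effort at which RER
#'   crosses 1.05.
#' @slot hrRest numeric, BPM.
#' @slot hrNoiseSd numeric, BPM breath-level noise.
#' @slot prematureFrac numeric, effort ceiling of a subject flagged with
#'   premature termination, as a fraction of the true maximal uptake.
#' @slot seed integer.
#' @export
setClass("CPETSimConfig",
  representation(basePower = "numeric", baseDuration = "numeric",
                 rampStep = "numeric", rampInterval = "numeric",
                 breathIntervalMean = "numeric", breathIntervalSd = "numeric",
                 vo2Rest = "numeric", vo2Gain = "numeric",
                 vo2TimeConstant = "numeric", vo2NoiseSd = "numeric",
                 rerRest = "numeric", rerCrossingFrac = "numeric",
                 hrRest = "numeric", hrNoiseSd = "numeric",
                 prematureFrac = "numeric", seed = "integer"))

setValidity("CPETSimConfig", function(object) {
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(object@rampStep > 0 && object@rampInterval > 0,
      "rampStep/rampInterval: ramp rate must be > 0")
  chk(object@baseDuration >= 0, "baseDuration: must be >= 0")
  chk(object@breathIntervalMean > 0, "breathIntervalMean: must be > 0")
  chk(object@breathIntervalSd >= 0, "breathIntervalSd: must be >= 0")
  chk(object@vo2TimeConstant > 0, "vo2TimeConstant: must be > 0")
  chk(object@vo2NoiseSd >= 0, "vo2NoiseSd: must be >= 0")
  chk(object@hrNoiseSd >= 0, "hrNoiseSd: must be >= 0")
  chk(object@rerCrossingFrac > 0 && object@rerCrossingFrac < 1,
      "rerCrossingFrac: must lie in (0, 1)")
  chk(object@rerRest > 0 && object@rerRest < 1.05,
      "rerRest: must lie in (0, 1.05)")
  chk(object@prematureFrac > 0 && object@prematureFrac < 1,
      "prematureFrac: must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname CPETSimConfig-class
#' @param basePower,baseDuration,rampStep,rampInterval see slots.
#' @param breathIntervalMean,breathIntervalSd,vo2Rest,vo2Gain see slots.
#' @param vo2TimeConstant,vo2NoiseSd,rerRest,rerCrossingFrac see slots.
#' @param hrRest,hrNoiseSd,prematureFrac,seed see slots.
#' @return A validated `CPETSimConfig`.
#' @export
#' @examples
#' cpetSimConfig(vo2NoiseSd = 0, hrNoiseSd = 0)
cpetSimConfig <- function(basePower = 50, baseDuration = 180, rampStep = 1,
                          rampInterval = 3.6, breathIntervalMean = 3,
                          breathIntervalSd = 0.3, vo2Rest = 350,
                          vo2Gain = 10.8, vo2TimeConstant = 30,
                          vo2NoiseSd = 60, rerRest = 0.8,
                          rerCrossingFrac = 0.75, hrRest = 60,
                          hrNoiseSd = 1.5, prematureFrac = 0.7, seed = 1L) {
  methods::new("CPETSimConfig", basePower = basePower,
               baseDuration = baseDuration, rampStep = rampStep,
               rampInterval = rampInterval,
               breathIntervalMean = breathIntervalMean,
               breathIntervalSd = breathIntervalSd, vo2Rest = vo2Rest,
               vo2Gain = vo2Gain, vo2TimeConstant = vo2TimeConstant,
               vo2NoiseSd = vo2NoiseSd, rerRest = rerRest,
               rerCrossingFrac = rerCrossingFrac, hrRest = hrRest,
               hrNoiseSd = hrNoiseSd, prematureFrac = prematureFrac,
               seed = as.integer(seed))
}

#' StudyConfig: full configuration of the synthetic validation study
#'
#' Bundles the cohort, SCG and CPET simulator configurations with the
#' measurement schedule (two rest recordings 5 min apart before CPET, one
#' post-exercise recording 5 min after), the cross-validation fold count for
#' the SCG model, and the master seed.
#'
#' @slot cohort a [CohortSpec-class].
#' @slot scg an [SCGSimConfig-class].
#' @slot cpet a [CPETSimConfig-class].
#' @slot nRestRecordings integer, rest recordings per subject (>= 1).
#' @slot nFolds integer, cross-validation folds for the SCG model fit.
#' @slot seed integer, master seed fanned out via [childSeed()].
#' @export
setClass("StudyConfig",
  representation(cohort = "CohortSpec", scg = "SCGSimConfig",
                 cpet = "CPETSimConfig", nRestRecordings = "integer",
                 nFolds = "integer", seed = "integer"))

setValidity("StudyConfig", function(object) {
  msg <- character()
  if (object@nRestRecordings < 1L)
    msg <- c(msg, "nRestRecordings: must be >= 1")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds: must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @rdname StudyConfig-class
#' @param cohort,scg,cpet,nRestRecordings,nFolds,seed see slots.
#' @return A validated `StudyConfig`.
#' @export
#' @examples
#' studyConfig(cohort = cohortSpec(n = 30, nPremature = 2L, nBattery = 1L))
studyConfig <- function(cohort = cohortSpec(), scg = scgSimConfig(),
                        cpet = cpetSimConfig(), nRestRecordings = 2L,
                        nFolds = 5L, seed = 1L) {
  methods::new("StudyConfig", cohort = cohort, scg = scg, cpet = cpet,
               nRestRecordings = as.integer(nRestRecordings),
               nFolds = as.integer(nFolds), seed = as.integer(seed))
}

#' Read a StudyConfig from a YAML file
#'
#' The YAML file may contain top-level blocks `cohort`, `scg`, `cpet` whose
#' entries are constructor arguments of [cohortSpec()], [scgSimConfig()] and
#' [cpetSimConfig()], plus scalar `nRestRecordings`, `nFolds` and `seed`.
#' Omitted entries keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A validated [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  build <- function(ctor, args) {
    if (is.null(args)) return(ctor())
    # YAML 1.1 parses a bare key `n` as boolean FALSE; map it back
    names(args)[names(args) %in% c("FALSE", "no")] <- "n"
    if ("vo2maxModel" %in% names(args))
      args$vo2maxModel <- unlist(args$vo2maxModel)
    do.call(ctor, args)
  }
  studyConfig(
    cohort = build(cohortSpec, y$cohort),
    scg = build(scgSimConfig, y$scg),
    cpet = build(cpetSimConfig, y$cpet),
    nRestRecordings = if (is.null(y$nRestRecordings)) 2L else y$nRestRecordings,
    nFolds = if (is.null(y$nFolds)) 5L else y$nFolds,
    seed = if (is.null(y$seed)) 1L else y$seed)
}
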