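# End-to-end synthetic validation study: generate -> process -> fit ->
# predict -> compare, emitting Table-1/2/3-shaped outputs.

# 32-bit FNV-1a hash of a raw vector, for config provenance.
fnv32 <- function(raw) {
  h <- 2166136261
  for (b in as.integer(raw)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Baseline (Table-1-style) summary: long data.frame of mean (SD) per
# variable for the whole cohort and the sedentary/active subgroups.
baselineTable <- function(df) {
  groups <- list(all = rep(TRUE, nrow(df)),
                 sedentary = !df$active_lifestyle,
                 active = df$active_lifestyle)
  numVars <- c(age = "age", height = "height", weight = "weight",
               bmi = "bmi", peak_power = "peak_power",
               vo2max_abs = "vo2max_abs", vo2max_rel = "vo2max_rel",
               scg_rest1 = "scg_rest1", scg_rest2 = "scg_rest2",
               scg_avg = "scg_avg", scg_post = "scg_post",
               friends = "friends", acsm = "acsm")
  numVars <- numVars[numVars %in% names(df)]
  rows <- lapply(names(groups), function(g) {
    sub <- df[groups[[g]], , drop = FALSE]
    head <- data.frame(
      variable = c("n", "female_pct"), group = g,
      mean = c(nrow(sub), round(100 * mean(sub$sex == 1), 1)),
      sd = NA_real_)
    body <- data.frame(
      variable = names(numVars), group = g,
      mean = vapply(numVars, function(v) mean(sub[[v]]), numeric(1L)),
      sd = vapply(numVars, function(v) stats::sd(sub[[v]]), numeric(1L)))
    rbind(head, body)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full synthetic validation study
#'
#' Generates a cohort, simulates the CPET reference test for every subject,
#' applies the exhaustion/battery exclusion rules, simulates the measurement
#' schedule for the included subjects (two rest SCG recordings before the
#' CPET, one post-exercise recording), processes every recording to an
#' ensemble beat and the four SCG features, fits the linear SCG model with
#' k-fold cross-validation (each subject is predicted by the model fitted
#' without their fold, since fitting and evaluating on the same subjects
#' would inflate agreement), evaluates the FRIENDS and ACSM benchmarks, and
#' compares every estimator to the CPET reference.
#'
#' The master seed is fanned out to per-stage and per-subject child seeds
#' via [childSeed()]; identical configurations give byte-identical reports.
#'
#' @param cfg a [StudyConfig-class].
#' @param outputDir optional directory: when given, intermediate CSVs
#'   (cohort, CPET results, feature table), the full-data model JSON and the
#'   report tables are written there.
#' @param verbose emit a message per excluded subject.
#' @return A [StudyReport-class].
#' @export
#' @examples
#' \donttest{
#' cfg <- studyConfig(cohort = cohortSpec(n = 40, nPremature = 3L,
#'                                        nBattery = 1L), seed = 7)
#' rep <- runStudy(cfg)
#' rep@agreement[, c("estimator", "bias", "mape", "r")]
#' }
runStudy <- function(cfg, outputDir = NULL, verbose = FALSE) {
  stopifnot(methods::is(cfg, "StudyConfig"))
  master <- cfg@seed
  stage <- function(name, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s', subject %s: %s", name, id,
                   conditionMessage(e)), call. = FALSE))
  }

  cohortSpecSeeded <- cfg@cohort
  cohortSpecSeeded@seed <- childSeed(master, "cohort")
  cohort <- generateCohort(cohortSpecSeeded)

  # reference test for every subject
  cpet <- do.call(rbind, lapply(seq_len(nrow(cohort)), function(i) {
    subj <- cohort[i, ]
    tr <- stage("cpet", subj$subject_id,
                simulateCpet(subj, cfg@cpet,
                             seed = childSeed(master, "cpet", i)))
    res <- checkExhaustion(computeVo2max(tr, subj$weight), subj$age)
    cbind(subject_id = subj$subject_id, res)
  }))
  full <- merge(cohort, cpet, by = "subject_id", sort = FALSE)
  full <- full[match(cohort$subject_id, full$subject_id), ]

  excl <- applyExclusions(full)
  included <- excl$included
  if (verbose) {
    out <- full[!full$subject_id %in% included$subject_id, ]
    for (i in seq_len(nrow(out)))
      message(sprintf("excluded %s: %s", out$subject_id[i],
                      if (!out$exhausted[i]) "premature termination"
                      else "battery failure"))
  }
  excludedDf <- data.frame(
    subject_id = setdiff(full$subject_id, included$subject_id))
  excludedDf$reason <- ifelse(
    !full$exhausted[match(excludedDf$subject_id, full$subject_id)],
    "premature_termination", "battery_failure")

  # measurement schedule for included subjects: rest recordings then post
  recNames <- c(paste0("rest", seq_len(cfg@nRestRecordings)), "post")
  feats <- list()
  beatsByRec <- stats::setNames(vector("list", length(recNames)), recNames)
  windows <- scgWindows()
  for (r in seq_along(recNames)) {
    cond <- if (recNames[r] == "post") "post_exercise" else "rest"
    beats <- lapply(seq_len(nrow(included)), function(i) {
      subj <- included[i, ]
      stage(paste0("scg_", recNames[r]), subj$subject_id, {
        rec <- simulateScg(subj, cond, cfg@scg,
                           seed = childSeed(master, "scg", i, r))
        rec@fiducials <- NULL  # force honest beat detection
        ensembleAverage(rec, windows = windows)
      })
    })
    beatsByRec[[recNames[r]]] <- beats
  }

  basis <- fitFeatureBasis(beatsByRec$rest1, windows = windows)
  for (r in recNames) {
    ft <- do.call(rbind, lapply(beatsByRec[[r]], extractFeatures,
                                basis = basis))
    ft$subject_id <- included$subject_id
    ft$recording <- r
    ft$n_beats_used <- vapply(beatsByRec[[r]], nBeatsUsed, integer(1L))
    feats[[r]] <- ft
  }
  featureTable <- do.call(rbind, feats)
  rownames(featureTable) <- NULL

  design <- function(r) {
    cbind(included[, c("subject_id", "sex", "age", "weight", "height")],
          feats[[r]][, c("rr_ms", "dia_ptp", "dia_morph", "sys_spec")])
  }
  d1 <- design("rest1")
  d1$vo2max_rel <- included$vo2max_rel

  # k-fold cross-validated predictions for every recording
  n <- nrow(included)
  folds <- withSeed(childSeed(master, "folds"),
                    sample(rep(seq_len(cfg@nFolds), length.out = n)))
  preds <- matrix(NA_real_, n, length(recNames),
                  dimnames = list(NULL, recNames))
  for (f in seq_len(cfg@nFolds)) {
    test <- folds == f
    model <- fitScgVo2Model(d1[!test, -1L])
    for (r in recNames)
      preds[test, r] <- predictVo2(model, design(r)[test, -1L])
  }
  finalModel <- fitScgVo2Model(d1[, -1L])

  predictions <- data.frame(
    subject_id = included$subject_id,
    vo2max_rel_ref = included$vo2max_rel,
    true_vo2max_rel = included$true_vo2max_rel,
    scg_rest1 = preds[, "rest1"],
    scg_rest2 = if ("rest2" %in% recNames) preds[, "rest2"] else NA_real_,
    scg_post = preds[, "post"],
    friends = predictFriends(included$age, included$sex, included$weight),
    acsm = predictAcsm(included$peak_power, included$weight))
  predictions$scg_avg <- if ("rest2" %in% recNames)
    (predictions$scg_rest1 + predictions$scg_rest2) / 2
  else predictions$scg_rest1

  estimators <- c("scg_rest1", "scg_rest2", "scg_avg", "scg_post",
                  "friends", "acsm")
  estimators <- estimators[!vapply(estimators, function(e)
    all(is.na(predictions[[e]])), logical(1L))]
  agreement <- do.call(rbind, lapply(estimators, function(e) {
    p <- pairedScores(predictions$subject_id, predictions[[e]],
                      predictions$vo2max_rel_ref)
    cbind(data.frame(estimator = e), agreementRow(agreementReport(p)))
  }))

  repeatability <- if ("rest2" %in% recNames) {
    icc <- iccAbsoluteAgreement(cbind(predictions$scg_rest1,
                                      predictions$scg_rest2))
    list(icc = icc@value, icc_variant = icc@variant,
         mape_pct = mean(100 * abs(predictions$scg_rest2 -
                                     predictions$scg_rest1) /
                           predictions$scg_rest1),
         rms = rmsDifference(pairedScores(predictions$subject_id,
                                          predictions$scg_rest2,
                                          predictions$scg_rest1)))
  } else list()

  baseDf <- cbind(included[, c("subject_id", "sex", "age", "height",
                               "weight", "bmi", "active_lifestyle")],
                  peak_power = included$peak_power,
                  vo2max_abs = included$vo2max_abs,
                  vo2max_rel = included$vo2max_rel,
                  predictions[, c("scg_rest1", "scg_rest2", "scg_avg",
                                  "scg_post", "friends", "acsm")])
  baseline <- baselineTable(baseDf)

  subCohort <- included[, c("subject_id", "sex", "age", "bmi",
                            "active_lifestyle")]
  subCohort$vo2max_rel_ref <- included$vo2max_rel
  pAvg <- pairedScores(predictions$subject_id, predictions$scg_avg,
                       predictions$vo2max_rel_ref)
  subgroups <- subgroupAnalysis(subCohort, pAvg)

  provenance <- list(
    seed = master, config_hash = fnv32(serialize(cfg, NULL)),
    nIncluded = nrow(included), package_version =
      as.character(utils::packageVersion("scgvo2")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    excluded = excludedDf)

  report <- methods::new("StudyReport", baseline = baseline,
                         agreement = agreement, subgroups = subgroups,
                         repeatability = repeatability,
                         exclusions = excl$tally,
                         predictions = predictions,
                         provenance = provenance)

  if (!is.null(outputDir)) {
    dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    writeCohortCsv(cohort, file.path(outputDir, "cohort.csv"))
    writeCohortCsv(cpet, file.path(outputDir, "cpet_results.csv"))
    writeFeatureTableCsv(featureTable, file.path(outputDir, "features.csv"))
    writeModelJson(finalModel, file.path(outputDir, "model.json"))
    writeBasisJson(basis, file.path(outputDir, "basis.json"))
    makeTables(report, outputDir)
  }
  report
}

#' Write the report tables of a study to disk
#'
#' Emits the Table-1-shaped baseline summary, the Table-2-shaped agreement
#' table, the Table-3-shaped subgroup table and the per-subject predictions
#' as CSV, plus repeatability, exclusion tally and provenance as JSON.
#'
#' @param report a [StudyReport-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
makeTables <- function(report, dir) {
  stopifnot(methods::is(report, "StudyReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    baseline = file.path(dir, "baseline.csv"),
    agreement = file.path(dir, "agreement.csv"),
    subgroups = file.path(dir, "subgroups.csv"),
    predictions = file.path(dir, "predictions.csv"),
    repeatability = file.path(dir, "repeatability.json"),
    exclusions = file.path(dir, "exclusions.json"),
    provenance = file.path(dir, "provenance.json"))
  utils::write.csv(report@baseline, paths["baseline"], row.names = FALSE)
  utils::write.csv(report@agreement, paths["agreement"], row.names = FALSE)
  utils::write.csv(report@subgroups, paths["subgroups"], row.names = FALSE)
  utils::write.csv(report@predictions, paths["predictions"],
                   row.names = FALSE)
  jsonlite::write_json(report@repeatability, paths["repeatability"],
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(report@exclusions), paths["exclusions"],
                       auto_unbox = TRUE, digits = NA)
  prov <- report@provenance
  prov$excluded <- NULL
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
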