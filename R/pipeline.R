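#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's settings with a single global seed from which
#' each stochastic stage derives its own sub-seed (simulation, fold
#' assignment, initialisation, shuffling, bootstrap); no stage reads
#' system entropy.
#'
#' @param n_train,n_test synthetic cohort sizes (ignored when manifests
#'   are supplied).
#' @param abnormal_fraction,severity_range,noise_sd cohort composition,
#'   see [cohortSpec()].
#' @param preset model scale preset, `"desk"` or `"full"`.
#' @param epochs,learning_rate,k_folds optional training overrides.
#' @param train_manifest,test_manifest optional manifest TSV paths to
#'   load pre-existing cohorts instead of simulating.
#' @param bootstrap_B bootstrap resamples for confidence intervals.
#' @param pt_grid decision-curve threshold probabilities.
#' @param render render a saliency overlay for one abnormal test record.
#' @param seed global seed.
#' @return A `RunConfig` list.
#' @export
runConfig <- function(n_train = 2000, n_test = 310,
                      abnormal_fraction = 0.27, severity_range = c(0.7, 1),
                      noise_sd = 0.01, preset = "desk", epochs = NULL,
                      learning_rate = NULL, k_folds = 5,
                      train_manifest = NULL, test_manifest = NULL,
                      bootstrap_B = 2000,
                      pt_grid = seq(0.01, 0.99, by = 0.01),
                      render = FALSE, seed = 1) {
  list(n_train = n_train, n_test = n_test,
       abnormal_fraction = abnormal_fraction,
       severity_range = severity_range, noise_sd = noise_sd,
       preset = preset, epochs = epochs, learning_rate = learning_rate,
       k_folds = k_folds, train_manifest = train_manifest,
       test_manifest = test_manifest, bootstrap_B = bootstrap_B,
       pt_grid = pt_grid, render = render, seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [runConfig()].
#' @return A `RunConfig` list (unknown keys are an error).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(runConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(runConfig, vals)
}

loadCohortFromManifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- readManifest(path)
  records <- lapply(seq_len(nrow(m)), function(i) {
    p <- m$path[i]
    fmt <- if (file.exists(paste0(p, ".json"))) "csvjson" else "wfdb"
    readECGRecord(p, fmt)
  })
  list(records = records, manifest = m)
}

#' Run the full screening pipeline
#'
#' simulate (or load) -> preprocess -> train -> evaluate -> explain.
#' Writes the run artefacts into `outdir`: `train_manifest.tsv`,
#' `test_manifest.tsv`, `summary.json`, `decision_curve.csv`,
#' `per_finding.tsv` and optionally `overlay.png`, and returns the
#' summary invisibly.  Re-running with an identical configuration and
#' seed reproduces the summary (single-threaded execution).
#'
#' The summary contains the test-set AUC, the Youden and
#' matched-sensitivity operating points with their screening metrics,
#' the McNemar comparison of model and comparator specificity at
#' matched sensitivity, and the per-finding table.
#'
#' @param config a [runConfig()].
#' @param outdir output directory (created if needed).
#' @param verbose log stage progress to stderr.
#' @return The summary list, invisibly.
#' @export
runPipeline <- function(config = runConfig(), outdir = tempfile("ecgrun"),
                        verbose = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(), "%H:%M:%S"),
                                            "] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage simulate")
  cohorts <- stage("simulate", {
    if (!is.null(config$train_manifest) || !is.null(config$test_manifest)) {
      list(train = loadCohortFromManifest(config$train_manifest),
           test = loadCohortFromManifest(config$test_manifest))
    } else {
      list(train = sampleCohort(cohortSpec(
             config$n_train, config$abnormal_fraction,
             severity_range = config$severity_range,
             noise_sd = config$noise_sd,
             seed = deriveSeed(config$seed, 11)),
             comparator = FALSE),  # comparator verdicts only needed on test
           test = sampleCohort(cohortSpec(
             config$n_test, config$abnormal_fraction,
             severity_range = config$severity_range,
             noise_sd = config$noise_sd,
             seed = deriveSeed(config$seed, 12))))
    }
  })
  writeManifest(cohorts$train$manifest, file.path(outdir, "train_manifest.tsv"))
  writeManifest(cohorts$test$manifest, file.path(outdir, "test_manifest.tsv"))

  say("stage preprocess (", length(cohorts$train$records), " train / ",
      length(cohorts$test$records), " test records)")
  cfg <- preprocessConfig()
  trainX <- stage("preprocess",
                  cohortTensors(cohorts$train$records, cfg,
                                keep_tensors = FALSE))
  cohorts$train$records <- NULL   # raw training waveforms are done with
  testX <- stage("preprocess",
                 cohortTensors(cohorts$test$records, cfg,
                               keep_tensors = isTRUE(config$render)))

  say("stage train (preset ", config$preset, ")")
  arch <- architectureConfig(preset = config$preset)
  tcfg <- trainConfig(config$preset, k_folds = config$k_folds,
                      seed = deriveSeed(config$seed, 21))
  if (!is.null(config$epochs)) tcfg$epochs <- as.integer(config$epochs)
  if (!is.null(config$learning_rate))
    tcfg$learning_rate <- config$learning_rate
  labelsTrain <- nzchar(cohorts$train$manifest$findings)
  ensemble <- stage("train",
    trainEnsemble(trainX, labelsTrain, cohorts$train$manifest$patient_id,
                  arch, tcfg, verbose = verbose))

  say("stage evaluate")
  truth <- nzchar(cohorts$test$manifest$findings)
  comp <- cohorts$test$manifest$comparator_flag
  prob <- predict(ensemble, testX)
  roc <- rocCurve(prob, truth)
  thrY <- youdenThreshold(roc)
  metY <- screeningMetrics(confusionTable(prob >= thrY, truth),
                           B = config$bootstrap_B,
                           seed = deriveSeed(config$seed, 31))
  compTab <- confusionTable(comp, truth)
  compMet <- screeningMetrics(compTab, B = config$bootstrap_B,
                              seed = deriveSeed(config$seed, 32))
  compSens <- compMet$estimate[compMet$statistic == "sensitivity"]
  thrM <- matchedSensitivityThreshold(prob, truth, compSens)
  metM <- screeningMetrics(confusionTable(prob >= thrM, truth),
                           B = config$bootstrap_B,
                           seed = deriveSeed(config$seed, 33))
  neg <- !truth
  b <- sum(!comp[neg] & (prob >= thrM)[neg])
  cc <- sum(comp[neg] & !(prob >= thrM)[neg])
  dc <- decisionCurve(prob, truth, comp, config$pt_grid)
  utils::write.csv(dc, file.path(outdir, "decision_curve.csv"),
                   row.names = FALSE)
  fndList <- strsplit(cohorts$test$manifest$findings, ",")
  perF <- tryCatch(
    perFindingReport(prob, fndList, comp, B = config$bootstrap_B,
                     seed = deriveSeed(config$seed, 34)),
    error = function(e) NULL)
  if (!is.null(perF))
    utils::write.table(perF, file.path(outdir, "per_finding.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  asNamed <- function(m) {
    v <- as.list(setNames(m$estimate, m$statistic))
    ci <- as.list(setNames(
      lapply(seq_len(nrow(m)), function(i) c(m$lower[i], m$upper[i])),
      paste0(m$statistic, "_ci")))
    c(v, ci)
  }
  summary <- list(
    seed = config$seed, preset = config$preset,
    n_train = length(cohorts$train$records),
    n_test = length(cohorts$test$records),
    prevalence = mean(truth), auc = roc$auc,
    youden_threshold = as.numeric(thrY),
    youden = asNamed(metY),
    comparator = asNamed(compMet),
    matched_threshold = as.numeric(thrM),
    matched_target_sensitivity = compSens,
    matched = asNamed(metM),
    mcnemar_discordant = list(b = b, c = cc),
    mcnemar_p = mcnemarTest(b, cc),
    selected_epochs = vapply(ensemble@folds, function(f) f$selectedEpoch,
                             numeric(1)),
    fingerprint = ensemble@fingerprint)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (isTRUE(config$render)) {
    say("stage explain")
    idx <- which(truth)[1]
    if (!is.na(idx)) {
      cam <- gradCAM(ensemble, testX, index = idx)
      hm <- camToTime(cam, testX$tensors[[idx]])
      stage("explain", renderOverlay(cohorts$test$records[[idx]], hm,
                                     file.path(outdir, "overlay.png"), cfg))
    }
  }
  say("done; artefacts in ", outdir)
  invisible(summary)
}
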