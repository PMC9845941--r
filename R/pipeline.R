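## End-to-end orchestration: synthesize (or read) a cohort, process the
## fNIRS recordings, score the behavioral logs, fit the risk model per
## subject, assemble the subject summary table, run the group-level
## statistics and write the report bundle (CSV tables + JSON summary +
## run log + manifest).

#' Pipeline configuration
#'
#' @param mode `"synthetic"` (generate a cohort) or `"files"` (read a
#'   cohort previously written with [writeCohortData()]).
#' @param inputDir directory of cohort files when `mode = "files"`.
#' @param cohort a [cohortConfig()] for synthetic mode.
#' @param nStarts multi-start count for the per-subject MLE.
#' @param catchExclusion exclude a subject's fit when catch accuracy
#'   falls below this fraction (attention QC; 6/8 by default).
#' @param regionMap,criteria fNIRS processing parameters.
#' @param seed integer seed for the whole run.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(mode = c("synthetic", "files"), inputDir = NULL,
                           cohort = cohortConfig(), nStarts = 20,
                           catchExclusion = 6 / 8,
                           regionMap = defaultRegionMap(),
                           criteria = artifactCriteria(), seed = 1) {
  mode <- match.arg(mode)
  if (mode == "files" && (is.null(inputDir) || !dir.exists(inputDir)))
    stop("mode 'files' needs an existing inputDir")
  structure(list(mode = mode, inputDir = inputDir, cohort = cohort,
                 nStarts = nStarts, catchExclusion = catchExclusion,
                 regionMap = regionMap, criteria = criteria,
                 seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Reads scalar overrides (`mode`, `inputDir`, `nStarts`,
#' `catchExclusion`, `seed`, and cohort `nAbstainers` / `nRelapsers` /
#' `components` / `closedLoop`) over the package defaults.
#'
#' @param path YAML file.
#' @return a [pipelineConfig()].
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cohortArgs <- y[["cohort"]]
  cfg <- do.call(cohortConfig, if (is.null(cohortArgs)) list()
                 else cohortArgs)
  args <- y[setdiff(names(y), "cohort")]
  do.call(pipelineConfig, c(args, list(cohort = cfg)))
}

#' Write a cohort to plain-text files
#'
#' Emits `cohort.csv` (covariates), `truth.csv`, `choices.csv`,
#' `behavior_gonogo.csv` / `behavior_nback.csv` / `behavior_vft.csv`,
#' per-subject fNIRS series under `fnirs/` (`<id>_<task>.csv` with a
#' `time_s` column plus one column per channel, and a `.json` events
#' sidecar), and `manifest.json` (seed, group sizes, config hash,
#' package version).
#'
#' @param cohort a [Cohort-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohortData <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(covariates(cohort), file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(groundTruth(cohort), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (nrow(choices(cohort)))
    utils::write.csv(choices(cohort), file.path(dir, "choices.csv"),
                     row.names = FALSE)
  beh <- behaviorLogs(cohort)
  for (nm in names(beh))
    utils::write.csv(beh[[nm]],
                     file.path(dir, paste0("behavior_", nm, ".csv")),
                     row.names = FALSE)
  recs <- recordings(cohort)
  if (length(recs)) {
    fdir <- file.path(dir, "fnirs")
    dir.create(fdir, showWarnings = FALSE)
    for (id in names(recs)) for (task in names(recs[[id]])) {
      rec <- recs[[id]][[task]]
      stem <- file.path(fdir, paste0(id, "_", task))
      m <- t(oxyHb(rec))
      df <- data.frame(time_s = (seq_len(nrow(m)) - 1) *
                         samplingInterval(rec))
      df[colnames(m)] <- round(m, 5)
      utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
      jsonlite::write_json(
        list(subject_id = subjectId(rec),
             sampling_interval_s = samplingInterval(rec),
             events = events(rec)),
        paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(seed = cohort@seed,
         n_abstainers = sum(covariates(cohort)$group == "abstainer"),
         n_relapsers = sum(covariates(cohort)$group == "relapser"),
         config_hash = .configHash(cohort@config),
         package_version = as.character(utils::packageVersion(
           "relapsemarkers"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a cohort written by [writeCohortData()]
#'
#' @param dir directory containing the cohort files.
#' @return A [Cohort-class] (missing streams come back empty; a
#'   missing/corrupt per-subject fNIRS file drops that subject's
#'   recording with a message rather than failing).
#' @export
readCohortData <- function(dir) {
  rd <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p) else data.frame()
  }
  covar <- rd("cohort.csv")
  if (!nrow(covar)) stop("no cohort.csv in ", dir)
  truth <- rd("truth.csv")
  beh <- list()
  for (nm in c("gonogo", "nback", "vft")) {
    b <- rd(paste0("behavior_", nm, ".csv"))
    if (nrow(b)) beh[[nm]] <- b
  }
  recs <- list()
  fdir <- file.path(dir, "fnirs")
  if (dir.exists(fdir)) {
    for (id in covar$subject_id) {
      rl <- list()
      for (task in c("gonogo", "vft")) {
        stem <- file.path(fdir, paste0(id, "_", task))
        if (!file.exists(paste0(stem, ".csv")) ||
            !file.exists(paste0(stem, ".json"))) next
        rl[[task]] <- tryCatch({
          df <- utils::read.csv(paste0(stem, ".csv"), check.names = FALSE)
          side <- jsonlite::read_json(paste0(stem, ".json"),
                                      simplifyVector = TRUE)
          m <- t(as.matrix(df[, setdiff(names(df), "time_s")]))
          FnirsRecording(m, side$sampling_interval_s,
                         as.data.frame(side$events), side$subject_id)
        }, error = function(e) {
          message("skipping unreadable recording ", stem, ": ",
                  conditionMessage(e))
          NULL
        })
      }
      if (length(rl)) recs[[id]] <- rl
    }
  }
  manifest <- file.path(dir, "manifest.json")
  seed <- if (file.exists(manifest))
    as.integer(jsonlite::read_json(manifest)$seed) else NA_integer_
  new("Cohort", covariates = covar, truth = truth, choices = rd("choices.csv"),
      behavior = beh, recordings = recs, config = list(), seed = seed)
}

#' Fit the risk model for every subject of a choice table
#'
#' @param choicesTab trial table with a `subject_id` column.
#' @param nStarts multi-start count.
#' @param catchExclusion QC threshold on catch accuracy; subjects below
#'   it are flagged (`qc_pass = FALSE`), not silently dropped.
#' @return data.frame: `subject_id`, `lambda`, `gamma`, `tau`, `nll`,
#'   `n_trials_used`, `converged`, `catch_accuracy`, `qc_pass`.
#' @export
fitCohortRiskModels <- function(choicesTab, nStarts = 20,
                                catchExclusion = 6 / 8) {
  out <- lapply(split(choicesTab, choicesTab$subject_id), function(tr) {
    fit <- fitRiskModel(tr, nStarts = nStarts)
    p <- riskParams(fit)
    acc <- catchAccuracy(fit)
    data.frame(subject_id = tr$subject_id[1],
               lambda = p[["lambda"]], gamma = p[["gamma"]],
               tau = p[["tau"]], nll = fit@nll,
               n_trials_used = fit@nTrialsUsed,
               converged = fit@converged,
               catch_accuracy = acc,
               qc_pass = is.na(acc) || acc >= catchExclusion)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Process all fNIRS recordings of a cohort
#'
#' @param cohort a [Cohort-class].
#' @param regionMap,criteria processing parameters.
#' @return list: `activations` (long data.frame over subjects), `qc`
#'   (rejected-channel counts), `failed` (subject ids that could not be
#'   processed).
#' @export
processCohortRecordings <- function(cohort, regionMap = defaultRegionMap(),
                                    criteria = artifactCriteria()) {
  recs <- recordings(cohort)
  acts <- list(); qc <- list(); failed <- character()
  for (id in names(recs)) {
    res <- tryCatch({
      do.call(rbind, lapply(recs[[id]], function(rec)
        suppressWarnings(processRecording(rec, regionMap, criteria))))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, id)
      next
    }
    acts[[id]] <- res
    nrej <- sum(vapply(recs[[id]], function(rec)
      sum(!suppressWarnings(rejectArtifactChannels(rec, criteria))$keep),
      numeric(1)))
    qc[[id]] <- data.frame(subject_id = id, channels_rejected = nrej)
  }
  activations <- if (length(acts)) do.call(rbind, acts) else NULL
  if (!is.null(activations)) rownames(activations) <- NULL
  list(activations = activations, qc = do.call(rbind, qc), failed = failed)
}

#' Assemble the per-subject summary table
#'
#' Joins covariates, region contrasts/VFT activations, behavioral
#' summaries and fitted risk parameters into the one-row-per-subject
#' table consumed by [runGroupAnalysis()]. Subjects missing a stream
#' keep `NA` in its columns.
#'
#' @param covar covariate table.
#' @param activations long activation table from
#'   [processCohortRecordings()].
#' @param behavior list of behavior logs (`gonogo`, `nback`, `vft`).
#' @param fits fit table from [fitCohortRiskModels()].
#' @return data.frame, one row per subject.
#' @export
buildSubjectSummary <- function(covar, activations = NULL,
                                behavior = NULL, fits = NULL) {
  out <- covar
  if (!is.null(activations) && NROW(activations)) {
    emo <- activations[activations$condition == "emotional", ]
    for (r in unique(emo$region))
      out[[paste0("contrast_", r)]] <-
        emo$contrast[match(paste(out$subject_id, r),
                           paste(emo$subject_id, emo$region))]
    vft <- activations[activations$condition == "vft", ]
    for (r in unique(vft$region))
      out[[paste0("vft_", r)]] <-
        vft$integral_oxyhb[match(paste(out$subject_id, r),
                                 paste(vft$subject_id, vft$region))]
  }
  if (!is.null(behavior) && length(behavior)) {
    bs <- do.call(rbind, lapply(unique(covar$subject_id), function(id) {
      g <- behavior$gonogo[behavior$gonogo$subject_id == id, ]
      n <- behavior$nback[behavior$nback$subject_id == id, ]
      v <- behavior$vft[behavior$vft$subject_id == id, ]
      if (!nrow(g) || !nrow(n)) return(NULL)
      cbind(subject_id = id, summarizeBehavior(g, n, v))
    }))
    out <- merge(out, bs, by = "subject_id", all.x = TRUE, sort = FALSE)
  }
  if (!is.null(fits) && NROW(fits))
    out <- merge(out,
                 fits[, c("subject_id", "lambda", "gamma", "tau",
                          "catch_accuracy", "qc_pass")],
                 by = "subject_id", all.x = TRUE, sort = FALSE)
  out[order(out$subject_id), , drop = FALSE]
}

.configHash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 10,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes synthesis (or file input) -> fNIRS processing -> behavioral
#' scoring -> per-subject risk-model fitting -> group statistics, and
#' writes the report bundle to `outDir`: stage CSVs, the group tables,
#' `summary.json`, `manifest.json` and `pipeline.log`. Stage timings
#' and QC counts (channels rejected, subjects dropped, catch-trial
#' failures) go to the log; a failed subject is dropped from the
#' affected tables, not fatal.
#'
#' @param config a [pipelineConfig()] or path to a YAML file.
#' @param outDir output directory.
#' @return the `groupAnalysis` result list, invisibly, with the
#'   subject summary attached as `$summary`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile()) {
  if (is.character(config)) config <- readPipelineConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logFile <- file.path(outDir, "pipeline.log")
  logLines <- character()
  note <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    logLines <<- c(logLines, line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    note(sprintf("stage %-10s %.1fs", name,
                 proc.time()[["elapsed"]] - t0))
    v
  }
  cohort <- stage("input", {
    if (config$mode == "synthetic")
      generateCohort(config$cohort, seed = config$seed)
    else readCohortData(config$inputDir)
  })
  covar <- covariates(cohort)
  note("subjects: ", nrow(covar))

  acts <- NULL; qcFnirs <- NULL
  if (length(recordings(cohort))) {
    pr <- stage("fnirs", processCohortRecordings(cohort, config$regionMap,
                                                 config$criteria))
    acts <- pr$activations
    qcFnirs <- pr$qc
    if (length(pr$failed))
      note("fNIRS processing failed, subject dropped from region tables: ",
           paste(pr$failed, collapse = ", "))
    missingRec <- setdiff(covar$subject_id,
                          unique(c(names(recordings(cohort)))))
    if (length(missingRec))
      note("no recording on file: ", paste(missingRec, collapse = ", "))
  }
  fits <- NULL
  if (nrow(choices(cohort))) {
    fits <- stage("riskfit",
                  fitCohortRiskModels(choices(cohort), config$nStarts,
                                      config$catchExclusion))
    if (any(!fits$qc_pass))
      note("catch-trial QC failures: ",
           paste(fits$subject_id[!fits$qc_pass], collapse = ", "))
  }
  summaryDf <- stage("summary",
                     buildSubjectSummary(covar, acts,
                                         behaviorLogs(cohort), fits))
  analysis <- stage("stats", runGroupAnalysis(summaryDf))

  utils::write.csv(summaryDf, file.path(outDir, "subject_summary.csv"),
                   row.names = FALSE)
  if (!is.null(acts))
    utils::write.csv(acts, file.path(outDir, "activations.csv"),
                     row.names = FALSE)
  if (!is.null(fits))
    utils::write.csv(fits, file.path(outDir, "fits.csv"),
                     row.names = FALSE)
  for (tb in c("demographics", "behavior", "fnirs", "risk")) {
    if (!is.null(analysis[[tb]]))
      utils::write.csv(analysis[[tb]],
                       file.path(outDir, paste0("table_", tb, ".csv")),
                       row.names = FALSE)
  }
  if (!is.null(analysis$correlations))
    utils::write.csv(analysis$correlations,
                     file.path(outDir, "table_correlations.csv"),
                     row.names = FALSE)
  if (!is.null(analysis$logistic))
    utils::write.csv(analysis$logistic$coefficients,
                     file.path(outDir, "table_logistic.csv"),
                     row.names = FALSE)

  summaryJson <- list(
    seed = config$seed,
    n_subjects = nrow(covar),
    n_abstainers = sum(covar$group == "abstainer"),
    n_relapsers = sum(covar$group == "relapser"),
    group_medians = if (!is.null(fits)) {
      byg <- split(summaryDf$lambda, summaryDf$group)
      lapply(byg, function(v) stats::median(v, na.rm = TRUE))
    },
    qc = list(
      channels_rejected = if (!is.null(qcFnirs))
        sum(qcFnirs$channels_rejected) else NA,
      catch_failures = if (!is.null(fits)) sum(!fits$qc_pass) else NA),
    tests = lapply(
      Filter(Negate(is.null),
             analysis[c("demographics", "behavior", "fnirs", "risk")]),
      function(tb) stats::setNames(as.list(round(tb$p.value, 6)),
                                   tb$variable)),
    logistic = if (!is.null(analysis$logistic)) list(
      odds_ratios = stats::setNames(
        as.list(round(analysis$logistic$coefficients$odds_ratio, 6)),
        analysis$logistic$coefficients$term),
      sensitivity = analysis$logistic$sensitivity,
      specificity = analysis$logistic$specificity,
      box_tidwell = analysis$boxTidwell$verdict))
  jsonlite::write_json(summaryJson, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  jsonlite::write_json(
    list(seed = config$seed, mode = config$mode,
         config_hash = .configHash(unclass(config)),
         package_version = as.character(utils::packageVersion(
           "relapsemarkers"))),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE)
  writeLines(logLines, logFile)
  analysis$summary <- summaryDf
  invisible(analysis)
}
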