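#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
NULL

.BLOCK_TYPES <- c("emotional", "nonemotional", "control",
                  "vft_production", "pre_baseline", "post_baseline")

#' Multichannel oxy-Hb recording with block events
#'
#' `FnirsRecording` holds one subject's continuous-wave fNIRS
#' oxy-hemoglobin series as a channel-by-time assay (concentration-change
#' units, e.g. mM·mm) together with the block-event schedule and the
#' sampling interval. It extends
#' [SummarizedExperiment::SummarizedExperiment] so the channel dimension
#' carries metadata in `rowData()`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; the single
#'   assay is named `"oxyHb"`, `metadata()` stores `samplingInterval`
#'   (seconds), `events` (data.frame with `type`, `onset_s`, `offset_s`)
#'   and `subjectId`.
#' @export
setClass("FnirsRecording", contains = "SummarizedExperiment")

.validFnirsRecording <- function(object) {
  msg <- character()
  if (!"oxyHb" %in% names(assays(object)))
    msg <- c(msg, "assay 'oxyHb' is required")
  md <- metadata(object)
  dt <- md$samplingInterval
  if (is.null(dt) || !is.numeric(dt) || length(dt) != 1L || dt <= 0)
    msg <- c(msg, "metadata 'samplingInterval' must be a positive scalar")
  ev <- md$events
  if (!is.data.frame(ev) ||
      !all(c("type", "onset_s", "offset_s") %in% names(ev)))
    msg <- c(msg, "metadata 'events' must have columns type/onset_s/offset_s")
  else {
    if (!all(ev$type %in% .BLOCK_TYPES))
      msg <- c(msg, paste0("event types must be one of: ",
                           paste(.BLOCK_TYPES, collapse = ", ")))
    if (any(ev$offset_s <= ev$onset_s))
      msg <- c(msg, "event offsets must exceed onsets")
    if (is.numeric(dt) && length(dt) == 1L && dt > 0) {
      dur <- ncol(object) * dt
      if (nrow(ev) && any(ev$onset_s < 0 | ev$offset_s > dur + 1e-9))
        msg <- c(msg, "events must lie within the recorded series")
    }
    if (nrow(ev) > 1L) {
      o <- order(ev$onset_s)
      if (any(ev$onset_s[o][-1L] < ev$offset_s[o][-nrow(ev)] - 1e-9))
        msg <- c(msg, "events must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("FnirsRecording", .validFnirsRecording)

#' Construct an FnirsRecording
#'
#' @param oxyHb numeric matrix, channels x time; rownames like `"ch22"`
#'   (or bare channel numbers) identify the measurement channels.
#' @param samplingInterval sampling interval in seconds (0.1 s for the
#'   ETG-4000 family of instruments).
#' @param events data.frame with columns `type` (one of `emotional`,
#'   `nonemotional`, `control`, `vft_production`, `pre_baseline`,
#'   `post_baseline`), `onset_s`, `offset_s`.
#' @param subjectId subject identifier.
#' @return A [FnirsRecording-class] object.
#' @examples
#' m <- matrix(rnorm(31 * 100), 31, 100,
#'             dimnames = list(paste0("ch", 22:52), NULL))
#' ev <- data.frame(type = "control", onset_s = 0, offset_s = 10)
#' FnirsRecording(m, 0.1, ev, "s01")
#' @export
FnirsRecording <- function(oxyHb, samplingInterval = 0.1,
                           events = data.frame(type = character(),
                                               onset_s = numeric(),
                                               offset_s = numeric()),
                           subjectId = NA_character_) {
  oxyHb <- as.matrix(oxyHb)
  if (is.null(rownames(oxyHb)))
    stop("oxyHb must carry channel rownames (e.g. 'ch22')")
  chan <- .channelNumbers(rownames(oxyHb))
  rownames(oxyHb) <- paste0("ch", chan)
  se <- SummarizedExperiment(
    assays = list(oxyHb = oxyHb),
    rowData = DataFrame(channel = chan, row.names = rownames(oxyHb)))
  md <- metadata(se)
  md$samplingInterval <- samplingInterval
  md$events <- events
  md$subjectId <- subjectId
  metadata(se) <- md
  new("FnirsRecording", se)
}

.channelNumbers <- function(x) {
  n <- suppressWarnings(as.integer(gsub("^ch", "", x)))
  if (any(is.na(n))) stop("channel names must be 'ch<number>' or numbers")
  n
}

#' @describeIn FnirsRecording channel-by-time oxy-Hb matrix
#' @param x an `FnirsRecording`
#' @export
setMethod("oxyHb", "FnirsRecording", function(x) assay(x, "oxyHb"))

#' @describeIn FnirsRecording block-event table
#' @export
setMethod("events", "FnirsRecording", function(x) metadata(x)$events)

#' @describeIn FnirsRecording sampling interval in seconds
#' @export
setMethod("samplingInterval", "FnirsRecording",
          function(x) metadata(x)$samplingInterval)

#' @describeIn FnirsRecording subject identifier
#' @export
setMethod("subjectId", "FnirsRecording", function(x) metadata(x)$subjectId)

#' @describeIn FnirsRecording integer channel ids
#' @export
setMethod("channelIds", "FnirsRecording", function(x) rowData(x)$channel)

setMethod("show", "FnirsRecording", function(object) {
  dt <- samplingInterval(object)
  cat("FnirsRecording for subject", subjectId(object), "\n")
  cat(" ", nrow(object), "channels x", ncol(object), "samples (",
      format(ncol(object) * dt, digits = 4), "s at dt =", dt, "s )\n")
  ev <- events(object)
  cat("  events:", if (nrow(ev)) paste(ev$type, collapse = ", ") else "none",
      "\n")
})

#' Risk-task trial schedule
#'
#' Ordered table of two-option gambles: 120 main (preference) trials in
#' 3 sessions plus 8 embedded catch trials in which one option dominates
#' (equal magnitude, strictly higher probability).
#'
#' @slot trials data.frame with one row per trial: `session`,
#'   `trial_index`, `p_a`, `x_a`, `p_b`, `x_b`, `is_catch`, `choice`,
#'   `rt_s`.
#' @slot nSessions number of sessions.
#' @export
setClass("TaskSchedule",
         representation(trials = "data.frame", nSessions = "integer"))

setValidity("TaskSchedule", function(object) {
  tr <- object@trials
  need <- c("session", "trial_index", "p_a", "x_a", "p_b", "x_b",
            "is_catch", "choice", "rt_s")
  msg <- character()
  if (!all(need %in% names(tr)))
    msg <- c(msg, paste("trials must have columns:",
                        paste(need, collapse = ", ")))
  else {
    if (any(tr$p_a <= 0 | tr$p_a > 1 | tr$p_b <= 0 | tr$p_b > 1))
      msg <- c(msg, "probabilities must lie in (0, 1]")
    if (any(tr$x_a <= 0 | tr$x_b <= 0))
      msg <- c(msg, "magnitudes must be positive")
    ct <- tr[tr$is_catch, , drop = FALSE]
    if (nrow(ct) &&
        any(is.na(dominantOption(ct$p_a, ct$x_a, ct$p_b, ct$x_b))))
      msg <- c(msg, "every catch trial must contain a dominant option")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn TaskSchedule trial table
#' @param x a `TaskSchedule`
#' @export
setMethod("trials", "TaskSchedule", function(x) x@trials)

#' @describeIn TaskSchedule number of sessions
#' @export
setMethod("nSessions", "TaskSchedule", function(x) x@nSessions)

#' @describeIn TaskSchedule utility normalization scale (largest
#'   magnitude on offer, in JPY)
#' @export
setMethod("xScale", "TaskSchedule",
          function(x) max(x@trials$x_a, x@trials$x_b))

setMethod("show", "TaskSchedule", function(object) {
  tr <- object@trials
  cat("TaskSchedule:", sum(!tr$is_catch), "main +", sum(tr$is_catch),
      "catch trials in", object@nSessions, "sessions\n")
  cat("  probabilities:", paste(range(tr$p_a, tr$p_b), collapse = "-"),
      " magnitudes (JPY):", paste(range(tr$x_a, tr$x_b), collapse = "-"),
      "\n")
})

#' Maximum-likelihood fit of the risk-preference model
#'
#' Result of [fitRiskModel()]: utility sensitivity (lambda), Prelec
#' weighting (gamma), softmax inverse temperature (tau), the negative
#' log-likelihood at the optimum and convergence diagnostics.
#'
#' @slot params named numeric: `lambda`, `gamma`, `tau`.
#' @slot nll negative log-likelihood (nats) at the optimum.
#' @slot nTrialsUsed number of trials entering the likelihood.
#' @slot converged did the best start converge.
#' @slot boundary any parameter at an optimization bound.
#' @slot nStarts number of multi-start optimizations.
#' @slot bestStart index of the winning start.
#' @slot catchAccuracy fraction of answered catch trials answered
#'   correctly (attention QC; `NA` if the data contain no catch trials).
#' @export
setClass("RiskModelFit",
         representation(params = "numeric", nll = "numeric",
                        nTrialsUsed = "integer", converged = "logical",
                        boundary = "logical", nStarts = "integer",
                        bestStart = "integer", catchAccuracy = "numeric"))

setValidity("RiskModelFit", function(object) {
  msg <- character()
  if (!all(c("lambda", "gamma", "tau") %in% names(object@params)))
    msg <- c(msg, "params must be named lambda/gamma/tau")
  else if (any(!is.finite(object@params)) || any(object@params <= 0))
    msg <- c(msg, "params must be strictly positive and finite")
  if (length(object@nll) != 1L || is.na(object@nll) || object@nll < 0)
    msg <- c(msg, "nll must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' @describeIn RiskModelFit fitted parameter vector (lambda, gamma, tau)
#' @param x a `RiskModelFit`
#' @export
setMethod("riskParams", "RiskModelFit", function(x) x@params)

#' @describeIn RiskModelFit catch-trial accuracy QC value
#' @export
setMethod("catchAccuracy", "RiskModelFit", function(x) x@catchAccuracy)

#' @describeIn RiskModelFit fitted coefficients (same as `riskParams`)
#' @param object a `RiskModelFit`
#' @param ... ignored
#' @export
setMethod("coef", "RiskModelFit", function(object, ...) object@params)

#' @describeIn RiskModelFit negative log-likelihood at the optimum
#' @export
setMethod("logLik", "RiskModelFit", function(object, ...) -object@nll)

setMethod("show", "RiskModelFit", function(object) {
  p <- object@params
  cat(sprintf(
    "RiskModelFit: lambda=%.3f gamma=%.3f tau=%.2f  (NLL %.2f, %d trials)\n",
    p["lambda"], p["gamma"], p["tau"], object@nll, object@nTrialsUsed))
  cat("  converged:", object@converged,
      if (object@boundary) " [parameter at bound]" else "", "\n")
  if (!is.na(object@catchAccuracy))
    cat(sprintf("  catch accuracy: %.0f%%\n", 100 * object@catchAccuracy))
})

#' Synthetic study cohort
#'
#' Container for one generated cohort: the participant covariate table,
#' the latent ground truth used by the generators (kept separate from
#' the "observed" streams so recovery tests cannot leak), the risk-task
#' choice table, the behavioral trial logs and the per-subject fNIRS
#' recordings.
#'
#' @slot covariates one row per subject (demographics + clinical scales).
#' @slot truth one row per subject of generating latent values.
#' @slot choices risk-task trial table over all subjects.
#' @slot behavior go/no-go, n-back and VFT trial logs over all subjects.
#' @slot recordings named list (by subject) of lists of
#'   [FnirsRecording-class] objects (`gonogo`, `vft`).
#' @slot config the [cohortConfig()] used.
#' @slot seed integer seed the cohort was generated under.
#' @export
setClass("Cohort",
         representation(covariates = "data.frame", truth = "data.frame",
                        choices = "data.frame", behavior = "list",
                        recordings = "list", config = "list",
                        seed = "integer"))

setValidity("Cohort", function(object) {
  msg <- character()
  cv <- object@covariates
  if (!all(c("subject_id", "group") %in% names(cv)))
    msg <- c(msg, "covariates must have subject_id and group columns")
  else if (!all(cv$group %in% c("abstainer", "relapser")))
    msg <- c(msg, "group must be 'abstainer' or 'relapser'")
  if (length(msg)) msg else TRUE
})

#' @describeIn Cohort participant covariate table
#' @param x a `Cohort`
#' @export
setMethod("covariates", "Cohort", function(x) x@covariates)

#' @describeIn Cohort generator ground-truth table
#' @export
setMethod("groundTruth", "Cohort", function(x) x@truth)

#' @describeIn Cohort risk-task choice table
#' @export
setMethod("choices", "Cohort", function(x) x@choices)

#' @describeIn Cohort behavioral trial logs (list: gonogo, nback, vft)
#' @export
setMethod("behaviorLogs", "Cohort", function(x) x@behavior)

#' @describeIn Cohort per-subject fNIRS recordings
#' @export
setMethod("recordings", "Cohort", function(x) x@recordings)

setMethod("show", "Cohort", function(object) {
  cv <- object@covariates
  cat("Cohort:", nrow(cv), "subjects (",
      sum(cv$group == "abstainer"), "abstainers /",
      sum(cv$group == "relapser"), "relapsers ), seed", object@seed, "\n")
  cat("  streams:",
      paste(c(if (nrow(object@choices)) "choices",
              if (length(object@behavior)) "behavior",
              if (length(object@recordings)) "fnirs"),
            collapse = ", "), "\n")
})
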