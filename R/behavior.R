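## Scoring of the behavioral streams: emotional go/no-go (false-alarm
## and omission error rates, RT over correct hits), n-back (% correct
## and RT per load) and verbal fluency (unique-word count).

#' Score go/no-go trial logs
#'
#' Per block: false-alarm rate = responses on no-go trials / all no-go
#' trials; omission error rate = withheld responses on go trials / all
#' go trials; mean reaction time over correct hits (responded go
#' trials) only. A block lacking either trial type gets missing rates.
#'
#' @param trialLog data.frame with columns `block` (`emotional`,
#'   `nonemotional`, `control`), `trial_type` (`go`/`nogo`),
#'   `responded` (logical), `rt_ms` (present iff responded).
#' @return data.frame per block: `block`, `false_alarm_rate`,
#'   `omission_error_rate`, `mean_rt_ms`, `n_go`, `n_nogo`.
#' @export
scoreGoNogo <- function(trialLog) {
  stopifnot(all(c("block", "trial_type", "responded", "rt_ms") %in%
                  names(trialLog)))
  out <- lapply(split(trialLog, trialLog$block), function(b) {
    go <- b[b$trial_type == "go", , drop = FALSE]
    nogo <- b[b$trial_type == "nogo", , drop = FALSE]
    ok <- nrow(go) > 0 && nrow(nogo) > 0
    hits <- go$responded
    data.frame(
      block = b$block[1],
      false_alarm_rate = if (ok) mean(nogo$responded) else NA_real_,
      omission_error_rate = if (ok) mean(!go$responded) else NA_real_,
      mean_rt_ms = if (any(hits)) mean(go$rt_ms[hits]) else NA_real_,
      n_go = nrow(go), n_nogo = nrow(nogo))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score n-back trial logs
#'
#' A trial is correct when the subject responds to a target (hit) or
#' withholds on a non-target (correct rejection); the percentage is
#' taken over all trials of a load, and RT over hits only.
#'
#' @param trialLog data.frame with columns `load` (1 or 2), `is_target`
#'   (logical), `responded` (logical), `rt_ms`.
#' @return data.frame per load: `load`, `percent_correct`,
#'   `mean_rt_ms`, `n_trials`.
#' @export
scoreNback <- function(trialLog) {
  if (!nrow(trialLog)) stop("empty n-back trial log")
  stopifnot(all(c("load", "is_target", "responded", "rt_ms") %in%
                  names(trialLog)))
  out <- lapply(split(trialLog, trialLog$load), function(b) {
    correct <- (b$is_target & b$responded) | (!b$is_target & !b$responded)
    hits <- b$is_target & b$responded
    data.frame(load = b$load[1],
               percent_correct = 100 * mean(correct),
               mean_rt_ms = if (any(hits)) mean(b$rt_ms[hits]) else NA_real_,
               n_trials = nrow(b))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Score verbal-fluency word events
#'
#' Counts words produced over the three 20-s production blocks,
#' excluding repeats and inflected variants of an earlier word: each
#' event carries an `inflection_key` (supplied by the transcription /
#' the generator; no linguistic processing happens here) and the score
#' is the number of unique keys.
#'
#' @param wordEvents data.frame with columns `word`, `block`,
#'   `inflection_key`.
#' @return integer count of valid words.
#' @export
scoreVft <- function(wordEvents) {
  stopifnot(all(c("word", "block", "inflection_key") %in%
                  names(wordEvents)))
  length(unique(wordEvents$inflection_key))
}

#' Summarize one subject's behavioral streams
#'
#' Collapses the three scored streams into the one-row summary used by
#' the group-comparison stage (emotional-task error rates, per-block
#' RTs, n-back accuracy/RT per load, VFT word count).
#'
#' @param gonogo trial log for [scoreGoNogo()].
#' @param nback trial log for [scoreNback()].
#' @param vft word events for [scoreVft()].
#' @return one-row data.frame.
#' @export
summarizeBehavior <- function(gonogo, nback, vft) {
  g <- scoreGoNogo(gonogo)
  n <- scoreNback(nback)
  pick <- function(df, key, col, val) {
    i <- which(df[[key]] == val)
    if (length(i)) df[[col]][i[1]] else NA_real_
  }
  data.frame(
    false_alarm_emotional = pick(g, "block", "false_alarm_rate", "emotional"),
    omission_emotional = pick(g, "block", "omission_error_rate", "emotional"),
    rt_emotional_ms = pick(g, "block", "mean_rt_ms", "emotional"),
    rt_nonemotional_ms = pick(g, "block", "mean_rt_ms", "nonemotional"),
    nback1_percent_correct = pick(n, "load", "percent_correct", 1),
    nback1_rt_ms = pick(n, "load", "mean_rt_ms", 1),
    nback2_percent_correct = pick(n, "load", "percent_correct", 2),
    nback2_rt_ms = pick(n, "load", "mean_rt_ms", 2),
    vft_words = scoreVft(vft))
}
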