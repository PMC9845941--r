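## Integral-mode processing of block-design oxy-Hb series:
## smooth (5 s moving average) -> reject artifact channels ->
## linear inter-baseline correction anchored on the last 10 s of the
## pre- and post-task periods -> integral of the corrected series over
## the task block -> region means -> emotional-minus-neutral contrast.

#' Default channel-to-region map
#'
#' The 31 frontotemporal channels (#22-52) of a 3x11 probe array split
#' into three regions: frontopolar (#25-28, 36-38, 46-49), left
#' frontotemporal (#29-31, 39-42, 50-52) and right frontotemporal
#' (#22-24, 32-35, 43-45).
#'
#' @return named list of integer channel vectors.
#' @export
defaultRegionMap <- function() {
  list(frontopolar = c(25:28, 36:38, 46:49),
       left_frontotemporal = c(29:31, 39:42, 50:52),
       right_frontotemporal = c(22:24, 32:35, 43:45))
}

.validateRegionMap <- function(map) {
  ch <- unlist(map, use.names = FALSE)
  if (anyDuplicated(ch)) stop("regions must be disjoint")
  if (!all(ch %in% 22:52)) stop("region channels must lie in 22..52")
  invisible(map)
}

#' Centered moving average with truncated edges
#'
#' Smooths short-term motion artifacts with a centered window of
#' `window` seconds (51 samples for 5 s at 10 Hz). At the edges the
#' window is truncated to the available samples, so the output has the
#' same length as the input and constant or affine signals pass through
#' unchanged in the interior.
#'
#' @param x numeric series.
#' @param window window length in seconds.
#' @param dt sampling interval in seconds.
#' @return smoothed series, same length as `x`.
#' @export
movingAverage <- function(x, window = 5, dt = 0.1) {
  if (!length(x)) stop("empty series")
  if (window < dt) stop("window must be at least one sampling interval")
  h <- floor(round(window / dt) / 2)
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Artifact-rejection criteria
#'
#' Deterministic replacements for manual blinded channel deletion:
#' a channel is rejected when (near-)flat, when more than
#' `spikeMaxCount` samples exceed `spikeZ` robust z-units from the
#' channel median (motion spikes), or when more than
#' `rhythmicPowerFrac` of its non-DC, detrended spectral power falls in
#' the `cardiacBand` (rhythmic noise).
#'
#' @param cardiacBand frequency band (Hz) treated as rhythmic noise.
#' @param rhythmicPowerFrac maximal tolerated band-power fraction.
#' @param spikeZ robust z threshold for a spike sample.
#' @param spikeMaxCount maximal tolerated number of spike samples.
#' @param flatlineSd standard deviation below which a channel is flat.
#' @return list of class `artifactCriteria`.
#' @export
artifactCriteria <- function(cardiacBand = c(0.6, 2.5),
                             rhythmicPowerFrac = 0.6,
                             spikeZ = 6, spikeMaxCount = 20,
                             flatlineSd = 1e-8) {
  structure(list(cardiacBand = cardiacBand,
                 rhythmicPowerFrac = rhythmicPowerFrac,
                 spikeZ = spikeZ, spikeMaxCount = spikeMaxCount,
                 flatlineSd = flatlineSd),
            class = "artifactCriteria")
}

.bandPowerFrac <- function(x, dt, band) {
  n <- length(x)
  t <- seq_len(n)
  x <- stats::residuals(stats::lm.fit(cbind(1, t), x))  # linear detrend
  P <- Mod(stats::fft(x))^2
  k <- 2:floor(n / 2)                                   # drop DC
  f <- (k - 1) / (n * dt)
  tot <- sum(P[k])
  if (tot <= 0) return(0)
  sum(P[k][f >= band[1] & f <= band[2]]) / tot
}

#' Reject artifact-contaminated channels
#'
#' @param rec a [FnirsRecording-class].
#' @param criteria an [artifactCriteria()].
#' @return data.frame with one row per channel: `channel`, `keep`,
#'   `reason` (`NA`, `"flatline"`, `"amplitude_spike"` or
#'   `"rhythmic_power"`).
#' @export
rejectArtifactChannels <- function(rec, criteria = artifactCriteria()) {
  dt <- samplingInterval(rec)
  m <- oxyHb(rec)
  if (ncol(m) * dt < 10) stop("need at least 10 s of data")
  out <- data.frame(channel = channelIds(rec), keep = TRUE,
                    reason = NA_character_)
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    if (stats::sd(x) < criteria$flatlineSd) {
      out$keep[i] <- FALSE; out$reason[i] <- "flatline"; next
    }
    ## spikes = fast excursions from the 1-s smoothed series; the scale
    ## floor (5% of the overall SD) keeps slow noiseless task responses
    ## from being mistaken for artifacts
    resid <- x - movingAverage(x, window = 1, dt = dt)
    scl <- max(stats::mad(resid), 0.05 * stats::sd(x), 1e-12)
    dev <- abs(resid - stats::median(resid)) / scl
    if (sum(dev > criteria$spikeZ) > criteria$spikeMaxCount) {
      out$keep[i] <- FALSE; out$reason[i] <- "amplitude_spike"; next
    }
    if (.bandPowerFrac(x, dt, criteria$cardiacBand) >
        criteria$rhythmicPowerFrac) {
      out$keep[i] <- FALSE; out$reason[i] <- "rhythmic_power"
    }
  }
  out
}

#' Dominant cardiac-band frequency (QC)
#'
#' Reports the frequency of the largest spectral peak in the cardiac
#' band, averaged over channels - a physiological-noise QC value, not a
#' group outcome.
#'
#' @inheritParams rejectArtifactChannels
#' @param band frequency band (Hz) to search.
#' @return frequency in Hz (`NA` if the band is empty).
#' @export
cardiacPeakFrequency <- function(rec, band = c(0.6, 2.5)) {
  dt <- samplingInterval(rec)
  m <- oxyHb(rec)
  n <- ncol(m)
  k <- 2:floor(n / 2)
  f <- (k - 1) / (n * dt)
  inb <- f >= band[1] & f <= band[2]
  if (!any(inb)) return(NA_real_)
  peaks <- apply(m, 1, function(x) {
    P <- Mod(stats::fft(x - mean(x)))^2
    f[inb][which.max(P[k][inb])]
  })
  mean(peaks)
}

#' Linear inter-baseline ("integral mode") correction
#'
#' Subtracts the straight line through two anchor points: the mean of
#' the last `anchor` seconds of the pre-task period (placed at the
#' center of that averaging window) and the mean of the last `anchor`
#' seconds of the post-task period. After correction both anchor
#' windows average to (numerically) zero, so the operation is
#' idempotent, and any affine trend between the baselines is removed.
#'
#' @param x numeric series; time of sample `i` is `(i - 1) * dt`.
#' @param preWindow,postWindow numeric `c(start, end)` in seconds of the
#'   pre- and post-task baseline periods; each must span at least
#'   `anchor` seconds and `preWindow` must end before `postWindow`
#'   begins.
#' @param dt sampling interval in seconds.
#' @param anchor length (s) of the baseline averaging window.
#' @return corrected series, same length as `x`.
#' @export
integralBaselineCorrect <- function(x, preWindow, postWindow, dt = 0.1,
                                    anchor = 10) {
  n <- length(x)
  if (!n) stop("empty series")
  if (preWindow[2] > postWindow[1] + 1e-9)
    stop("pre-task window must end before the post-task window begins ",
         "(windows must flank the task period)")
  if (diff(preWindow) < anchor - 1e-9 || diff(postWindow) < anchor - 1e-9)
    stop("each baseline window must span at least ", anchor, " s")
  times <- (seq_len(n) - 1) * dt
  anchorIdx <- function(w) {
    idx <- which(times >= w[2] - anchor - 1e-9 & times < w[2] - 1e-9)
    if (!length(idx)) stop("baseline anchor window contains no samples")
    idx
  }
  i1 <- anchorIdx(preWindow); i2 <- anchorIdx(postWindow)
  m1 <- mean(x[i1]); m2 <- mean(x[i2])
  ## anchor abscissa = mean sample time of the averaging window, so the
  ## corrected window means are exactly zero (=> idempotence)
  t1 <- mean(times[i1]); t2 <- mean(times[i2])
  x - (m1 + (m2 - m1) / (t2 - t1) * (times - t1))
}

#' Integral oxy-Hb over a task window
#'
#' Rectangle-rule area `sum(x[t in window]) * dt` of the
#' baseline-corrected series over the task block (units:
#' concentration x seconds). The window is half-open, `[onset, offset)`.
#'
#' @param x corrected numeric series.
#' @param taskWindow numeric `c(onset, offset)` in seconds.
#' @param dt sampling interval in seconds.
#' @return integral value.
#' @export
integralOxyHb <- function(x, taskWindow, dt = 0.1) {
  times <- (seq_along(x) - 1) * dt
  idx <- times >= taskWindow[1] - 1e-9 & times < taskWindow[2] - 1e-9
  if (!any(idx)) stop("task window contains no samples")
  sum(x[idx]) * dt
}

#' Aggregate channel integrals into region activations
#'
#' Mean of the per-channel integral values over the surviving channels
#' of each region; a region with no surviving channel gets `NA` (with a
#' warning) rather than a fabricated value.
#'
#' @param channelIntegrals named numeric vector (`"ch22"`, ...) of
#'   per-channel integrals.
#' @param regionMap named list of integer channel ids (see
#'   [defaultRegionMap()]).
#' @param keep logical vector parallel to `channelIntegrals` (default:
#'   keep all).
#' @return data.frame `region`, `integral_oxyhb`, `n_channels_used`.
#' @export
regionIntegral <- function(channelIntegrals, regionMap = defaultRegionMap(),
                           keep = rep(TRUE, length(channelIntegrals))) {
  .validateRegionMap(regionMap)
  have <- .channelNumbers(names(channelIntegrals))
  if (!all(unlist(regionMap) %in% have))
    stop("region map names a channel absent from the recording")
  out <- lapply(names(regionMap), function(r) {
    idx <- which(have %in% regionMap[[r]] & keep)
    if (!length(idx)) {
      warning("all channels rejected in region ", r, "; value missing")
      data.frame(region = r, integral_oxyhb = NA_real_,
                 n_channels_used = 0L)
    } else {
      data.frame(region = r,
                 integral_oxyhb = mean(channelIntegrals[idx]),
                 n_channels_used = length(idx))
    }
  })
  do.call(rbind, out)
}

#' Emotional-minus-neutral contrast
#'
#' Region-wise difference of integral activations: emotional-face block
#' minus neutral-face block, removing the shared sensorimotor component
#' of the response.
#'
#' @param emotional,neutral data.frames as returned by
#'   [regionIntegral()] (same regions, same subject).
#' @return data.frame `region`, `contrast`.
#' @export
emotionContrast <- function(emotional, neutral) {
  if (!identical(emotional$region, neutral$region))
    stop("emotional and neutral activations must cover the same regions")
  data.frame(region = emotional$region,
             contrast = emotional$integral_oxyhb - neutral$integral_oxyhb)
}

## locate baseline blocks flanking a task event
.flankWindows <- function(ev, onset, offset) {
  base <- ev[ev$type %in% c("pre_baseline", "post_baseline", "control"), ,
             drop = FALSE]
  pre <- base[base$offset_s <= onset + 1e-9, , drop = FALSE]
  post <- base[base$onset_s >= offset - 1e-9, , drop = FALSE]
  if (!nrow(pre) || !nrow(post))
    stop("task block has no flanking baseline/control blocks")
  pre <- pre[which.max(pre$offset_s), ]
  post <- post[which.min(post$onset_s), ]
  list(pre = c(pre$onset_s, pre$offset_s),
       post = c(post$onset_s, post$offset_s))
}

#' Process one recording into region activations
#'
#' Full integral-mode pipeline for one subject: artifact-channel
#' rejection on the raw series, 5-s moving average, per-task-block
#' linear inter-baseline correction, per-channel integral over the task
#' block, region aggregation, and the emotional-minus-neutral contrast
#' when both face blocks are present. Contiguous `vft_production`
#' events are merged into a single `vft` task window.
#'
#' @param rec a [FnirsRecording-class].
#' @param regionMap named list of channel ids per region.
#' @param criteria an [artifactCriteria()].
#' @param maWindow moving-average window (s).
#' @return data.frame with columns `subject_id`, `region`, `condition`,
#'   `integral_oxyhb`, `contrast` (filled on `emotional` rows),
#'   `n_channels_used`.
#' @export
processRecording <- function(rec, regionMap = defaultRegionMap(),
                             criteria = artifactCriteria(), maWindow = 5) {
  dt <- samplingInterval(rec)
  ev <- events(rec)
  mask <- rejectArtifactChannels(rec, criteria)
  sm <- t(apply(oxyHb(rec), 1, movingAverage, window = maWindow, dt = dt))
  rownames(sm) <- rownames(oxyHb(rec))

  taskList <- list()
  for (type in c("emotional", "nonemotional")) {
    tev <- ev[ev$type == type, , drop = FALSE]
    if (nrow(tev))
      taskList[[type]] <- c(tev$onset_s[1], tev$offset_s[1])
  }
  vft <- ev[ev$type == "vft_production", , drop = FALSE]
  if (nrow(vft)) taskList[["vft"]] <- c(min(vft$onset_s), max(vft$offset_s))

  res <- list()
  for (cond in names(taskList)) {
    tw <- taskList[[cond]]
    fl <- .flankWindows(ev, tw[1], tw[2])
    ints <- apply(sm, 1, function(x)
      integralOxyHb(
        integralBaselineCorrect(x, fl$pre, fl$post, dt = dt), tw, dt = dt))
    ri <- regionIntegral(ints, regionMap, keep = mask$keep)
    ri$condition <- cond
    res[[cond]] <- ri
  }
  if (!length(res)) stop("recording contains no task blocks")
  out <- do.call(rbind, res)
  out$subject_id <- subjectId(rec)
  out$contrast <- NA_real_
  if (all(c("emotional", "nonemotional") %in% names(res))) {
    ctr <- emotionContrast(res$emotional, res$nonemotional)
    i <- out$condition == "emotional"
    out$contrast[i] <- ctr$contrast[match(out$region[i], ctr$region)]
  }
  rownames(out) <- NULL
  out[, c("subject_id", "region", "condition", "integral_oxyhb",
          "contrast", "n_channels_used")]
}
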