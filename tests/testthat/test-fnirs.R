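test_that("moving average: constants, impulse, ramps, oracle agreement", {
  expect_equal(movingAverage(rep(3, 200)), rep(3, 200))
  # unit impulse at 10 Hz with a 5-s window -> plateau of 1/51
  x <- numeric(301); x[151] <- 1
  sm <- movingAverage(x)
  expect_equal(sm[151], 1 / 51)
  expect_equal(sum(sm[126:176] > 0), 51)
  # affine signals are preserved away from the edges
  ramp <- seq(0, 10, length.out = 400)
  smr <- movingAverage(ramp)
  expect_equal(smr[26:375], ramp[26:375], tolerance = 1e-10)
  # independent oracle: zoo partial centered rolling mean
  skip_if_not_installed("zoo")
  y <- withr::with_seed(1, rnorm(300))
  expect_equal(movingAverage(y),
               zoo::rollapply(y, 51, mean, partial = TRUE, align = "center"),
               tolerance = 1e-12)
  expect_error(movingAverage(numeric(0)), "empty")
  expect_error(movingAverage(1:10, window = 0.01), "window")
})

test_that("artifact rejection identifies rhythmic, spiky and flat channels", {
  n <- 1200
  t <- (seq_len(n) - 1) * 0.1
  hrf_like <- 0.5 * sin(2 * pi * t / 120)           # slow clean signal
  withr::with_seed(2, {
    clean <- hrf_like + rnorm(n, 0, 0.2)
    cardiac <- 3 * sin(2 * pi * 1.1 * t) + rnorm(n, 0, 0.1)
    spiky <- rnorm(n, 0, 0.1)
    spiky[sample.int(n, 40)] <- spiky[sample.int(n, 40)] + 8
  })
  m <- rbind(ch22 = clean, ch23 = cardiac, ch24 = spiky,
             ch25 = rep(0, n))
  rec <- FnirsRecording(m, 0.1,
                        data.frame(type = "control", onset_s = 0,
                                   offset_s = 120), "QC")
  mask <- rejectArtifactChannels(rec)
  expect_true(mask$keep[mask$channel == 22])
  expect_false(mask$keep[mask$channel == 23])
  expect_identical(mask$reason[mask$channel == 23], "rhythmic_power")
  expect_false(mask$keep[mask$channel == 24])
  expect_identical(mask$reason[mask$channel == 24], "amplitude_spike")
  expect_false(mask$keep[mask$channel == 25])
  expect_identical(mask$reason[mask$channel == 25], "flatline")
  # the spectral-peak QC finds the cardiac frequency
  recC <- FnirsRecording(rbind(ch22 = cardiac), 0.1,
                         data.frame(type = "control", onset_s = 0,
                                    offset_s = 120), "QC")
  expect_equal(cardiacPeakFrequency(recC), 1.1, tolerance = 0.02)
})

test_that("inter-baseline correction: flats, lines, boxcars, idempotence", {
  dt <- 0.1
  n <- 900                                         # 90 s
  pre <- c(0, 30); post <- c(60, 90)
  # flat series -> all zeros
  expect_equal(integralBaselineCorrect(rep(4.2, n), pre, post, dt),
               rep(0, n))
  # a pure line between the baselines is annihilated
  times <- (seq_len(n) - 1) * dt
  line <- 2 + 0.3 * times
  expect_equal(integralBaselineCorrect(line, pre, post, dt), rep(0, n),
               tolerance = 1e-10)
  # boxcar of height 2 over the task atop baseline 1 survives unchanged
  x <- rep(1, n); x[times >= 30 & times < 60] <- 3
  cor1 <- integralBaselineCorrect(x, pre, post, dt)
  expect_equal(cor1[times >= 30 & times < 60], rep(2, 300))
  expect_equal(cor1[times < 30], rep(0, 300))
  # corrected anchor-window means are zero; correction is idempotent
  y <- withr::with_seed(3, cumsum(rnorm(n, 0, 0.1)))
  c1 <- integralBaselineCorrect(y, pre, post, dt)
  expect_equal(mean(c1[times >= 20 & times < 30]), 0, tolerance = 1e-12)
  expect_equal(mean(c1[times >= 80 & times < 90]), 0, tolerance = 1e-12)
  expect_equal(integralBaselineCorrect(c1, pre, post, dt), c1,
               tolerance = 1e-10)
  expect_error(integralBaselineCorrect(y, c(40, 70), c(0, 30), dt),
               "flank")
  expect_error(integralBaselineCorrect(y, c(0, 5), post, dt), "10")
})

test_that("integral value: rectangle rule and quadrature oracle", {
  x <- rep(2, 900)
  expect_equal(integralOxyHb(x, c(0, 60)), 120)
  expect_equal(integralOxyHb(rep(0, 900), c(10, 50)), 0)
  # smooth response: rectangle rule within 1% of the trapezoid oracle
  t <- seq(0, 89.9, by = 0.1)
  resp <- dgamma(t - 10, shape = 6, rate = 1)
  rect <- integralOxyHb(resp, c(10, 60))
  idx <- which(t >= 10 & t < 60)
  trap <- sum((resp[idx][-1] + resp[idx][-length(idx)]) / 2) * 0.1
  expect_lt(abs(rect - trap) / trap, 0.01)
  expect_error(integralOxyHb(x, c(200, 300)), "window")
})

test_that("region aggregation: means, permutation invariance, rejection", {
  rm <- defaultRegionMap()
  ch <- sort(unlist(rm))
  vals <- setNames(rep(7, length(ch)), paste0("ch", ch))
  ri <- regionIntegral(vals, rm)
  expect_equal(ri$integral_oxyhb, rep(7, 3))
  expect_equal(ri$n_channels_used,
               vapply(rm[ri$region], length, integer(1)),
               ignore_attr = TRUE)
  # order permutation does not change the result
  valsR <- withr::with_seed(4, setNames(rnorm(length(ch)),
                                        paste0("ch", ch)))
  perm <- withr::with_seed(5, sample(seq_along(valsR)))
  expect_equal(regionIntegral(valsR, rm)$integral_oxyhb,
               regionIntegral(valsR[perm], rm)$integral_oxyhb)
  # rejecting one of the 10 right-FT channels -> hand mean over the
  # remaining 9, other regions untouched
  keep <- rep(TRUE, length(ch))
  keep[which(ch == 33)] <- FALSE
  ri2 <- regionIntegral(valsR, rm, keep)
  rf <- rm$right_frontotemporal
  expect_equal(
    ri2$integral_oxyhb[ri2$region == "right_frontotemporal"],
    mean(valsR[paste0("ch", setdiff(rf, 33))]))
  expect_identical(
    ri2$n_channels_used[ri2$region == "right_frontotemporal"], 9L)
  expect_equal(ri2$integral_oxyhb[ri2$region == "frontopolar"],
               regionIntegral(valsR, rm)$integral_oxyhb[
                 ri$region == "frontopolar"])
  # all channels of a region rejected -> NA with warning
  keep3 <- !(ch %in% rm$frontopolar)
  expect_warning(ri3 <- regionIntegral(valsR, rm, keep3), "frontopolar")
  expect_true(is.na(ri3$integral_oxyhb[ri3$region == "frontopolar"]))
  # unknown channel in the map -> error
  expect_error(regionIntegral(valsR[1:5], rm), "absent")
})

test_that("emotion contrast subtracts neutral from emotional per region", {
  a <- data.frame(region = c("r1", "r2"), integral_oxyhb = c(30.5, 10))
  b <- data.frame(region = c("r1", "r2"), integral_oxyhb = c(0, 10))
  ctr <- emotionContrast(a, b)
  expect_equal(ctr$contrast, c(30.5, 0))
  expect_error(emotionContrast(a, b[2:1, ]), "regions")
})

test_that("noiseless generator closes the loop: pipeline recovers truth", {
  quiet <- fnirsDesign(pinkSd = 0, whiteSd = 0, cardiacAmp = 0,
                       spikeRatePerMin = 0, channelGainSd = 0)
  truth <- makeTruthRow(contrast = -33.6, vft = 25)
  rec <- generateFnirsRecording(truth, quiet, "gonogo", seed = 6)
  out <- processRecording(rec)
  emo <- out[out$condition == "emotional", ]
  expect_equal(emo$contrast, rep(-33.6, 3), tolerance = 1e-6)
  expect_true(all(out$n_channels_used ==
                    lengths(defaultRegionMap())[out$region]))
  vrec <- generateFnirsRecording(truth, quiet, "vft", seed = 7)
  vout <- processRecording(vrec)
  expect_equal(vout$integral_oxyhb, rep(25, 3), tolerance = 1e-6)
})

test_that("pipeline is linear: scaling the raw series scales every output", {
  truth <- makeTruthRow(contrast = 40)
  rec <- generateFnirsRecording(truth, fnirsDesign(spikeRatePerMin = 0),
                                "gonogo", seed = 8)
  out1 <- processRecording(rec)
  k <- 2.5
  recK <- FnirsRecording(k * oxyHb(rec), samplingInterval(rec),
                         events(rec), subjectId(rec))
  outK <- processRecording(recK)
  expect_equal(outK$integral_oxyhb, k * out1$integral_oxyhb,
               tolerance = 1e-8)
  expect_equal(outK$contrast, k * out1$contrast, tolerance = 1e-8)
})

test_that("injected right-FT group difference is recovered in replicates", {
  # fNIRS-only cohorts: relapser median right-FT contrast below the
  # abstainer median in every replicate at the calibrated effect size
  ok <- vapply(1:6, function(s) {
    ch <- generateCohort(cohortConfig(components = "fnirs"), seed = 200 + s)
    acts <- processCohortRecordings(ch)$activations
    emo <- acts[acts$condition == "emotional" &
                  acts$region == "right_frontotemporal", ]
    grp <- covariates(ch)$group[match(emo$subject_id,
                                      covariates(ch)$subject_id)]
    median(emo$contrast[grp == "relapser"], na.rm = TRUE) <
      median(emo$contrast[grp == "abstainer"], na.rm = TRUE)
  }, logical(1))
  expect_true(all(ok))
})
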