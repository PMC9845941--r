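test_that("Prelec weighting: identity, fixed point, monotonicity, domains", {
  p <- seq(0.05, 1, by = 0.05)
  expect_equal(prelecWeight(p, 1), p)                 # gamma = 1 identity
  for (g in c(0.3, 0.7, 1, 1.5, 2.7))                 # fixed point at 1/e
    expect_equal(prelecWeight(exp(-1), g), exp(-1), tolerance = 1e-12)
  for (g in c(0.4, 1.3)) {                            # monotone on a grid
    w <- prelecWeight(p, g)
    expect_true(all(diff(w) > 0))
    expect_true(all(w > 0 & w <= 1))
  }
  expect_equal(prelecWeight(1, 2.2), 1)
  # frozen closed form: exp(-(ln 10)^0.5)
  expect_equal(prelecWeight(0.1, 0.5), 0.2192753, tolerance = 1e-6)
  expect_error(prelecWeight(0, 1), "p")
  expect_error(prelecWeight(1.01, 1), "p")
  expect_error(prelecWeight(0.5, 0), "gamma")
})

test_that("power utility and subjective value match closed forms", {
  expect_equal(utilityPower(5000, 1, 5000), 1)
  expect_equal(utilityPower(1250, 0.5, 5000), 0.5)
  # 0.5^0.530, lambda at the relapse-group median
  expect_equal(utilityPower(2500, 0.530, 5000), 0.6925547, tolerance = 1e-6)
  expect_error(utilityPower(-1, 1, 5000))
  # expected-value case at lambda = gamma = 1
  expect_equal(subjectiveValue(0.5, 5000, 1, 1, 5000), 0.5)
  # certain maximal reward is worth exactly 1 for any gamma
  expect_equal(subjectiveValue(1, 5000, 0.241, 0.7, 5000), 1)
  # frozen: exp(-(-ln 0.3)^0.5) * 1
  expect_equal(subjectiveValue(0.3, 5000, 0.5, 0.5, 5000), 0.3337854,
               tolerance = 1e-6)
})

test_that("softmax choice rule: symmetry, limit, logistic value", {
  pars <- riskPreferenceParams(0.8, 1.2, 5)
  expect_equal(
    choiceProbability(0.5, 3000, 0.5, 3000, pars, 10000), 0.5)
  parsHot <- riskPreferenceParams(1, 1, 1e6)
  expect_gt(choiceProbability(0.9, 5000, 0.1, 4000, parsHot, 5000), 0.9999)
  # tau * (SV_A - SV_B) = 1  ->  1 / (1 + e^-1)
  p <- choiceProbability(1, 7000, 1, 5000, riskPreferenceParams(1, 1, 5),
                         10000)
  expect_equal(p, 0.7310586, tolerance = 1e-6)
})

test_that("negative log-likelihood equals brute-force per-trial summation", {
  pars <- riskPreferenceParams(0.6, 0.8, 12)
  tr <- makeTrials(120, seed = 7)
  expect_equal(negLogLik(tr, pars, 10000), oracleNll(tr, pars, 10000),
               tolerance = 1e-10)
  # catch and no-response trials are excluded from the sum
  tr2 <- tr
  tr2$is_catch[1:8] <- TRUE
  tr2$choice[9:12] <- "none"
  expect_equal(negLogLik(tr2, pars, 10000), oracleNll(tr2, pars, 10000),
               tolerance = 1e-10)
  expect_lt(negLogLik(tr2, pars, 10000), negLogLik(tr, pars, 10000))
  # single trial at P = 0.5 -> ln 2
  one <- data.frame(p_a = 0.5, x_a = 3000, p_b = 0.5, x_b = 3000,
                    is_catch = FALSE, choice = "A")
  expect_equal(negLogLik(one, pars, 10000), log(2))
  # zero usable trials -> error
  none <- one; none$choice <- "none"
  expect_error(negLogLik(none, pars, 10000), "usable")
  # a near-deterministic agent is almost perfectly predicted by its own
  # parameters (a couple of near-tie trials keep the NLL just above 0,
  # far below the ~83 nats of random guessing)
  sch <- buildTaskSchedule(seed = 3)
  hot <- riskPreferenceParams(1, 1, 1000)
  obs <- simulateAgent(sch, hot, seed = 4, lapseRate = 0, noneRate = 0)
  expect_lt(negLogLik(obs, hot), 2)
})

test_that("likelihood and fit are invariant to trial order", {
  pars <- riskPreferenceParams(0.7, 1.1, 9)
  sch <- buildTaskSchedule(seed = 11)
  obs <- simulateAgent(sch, pars, seed = 12)
  perm <- withr::with_seed(13, obs[sample.int(nrow(obs)), ])
  expect_equal(negLogLik(obs, pars), negLogLik(perm, pars),
               tolerance = 1e-10)
  f1 <- fitRiskModel(obs)
  f2 <- fitRiskModel(perm)
  expect_equal(riskParams(f1), riskParams(f2), tolerance = 1e-6)
})

test_that("task schedule has the designed structure", {
  sch <- buildTaskSchedule(seed = 5)
  tr <- trials(sch)
  expect_identical(nrow(tr), 128L)
  expect_identical(sum(!tr$is_catch), 120L)
  expect_identical(sum(tr$is_catch), 8L)
  expect_identical(sort(unique(tr$session)), 1:3)
  expect_true(all(table(tr$session[!tr$is_catch]) == 40))
  # exactly one catch inside every block of 15 main trials
  mainCount <- cumsum(!tr$is_catch)
  block <- pmin(ceiling(pmax(mainCount, 1) / 15), 8)
  expect_true(all(table(block[tr$is_catch]) == 1))
  # no main trial is dominated; every catch trial is
  main <- tr[!tr$is_catch, ]
  expect_true(all(is.na(
    dominantOption(main$p_a, main$x_a, main$p_b, main$x_b))))
  ct <- tr[tr$is_catch, ]
  expect_true(all(!is.na(
    dominantOption(ct$p_a, ct$x_a, ct$p_b, ct$x_b))))
  expect_true(all(ct$x_a == ct$x_b))
  # determinism under a fixed seed
  expect_identical(trials(buildTaskSchedule(seed = 5)), tr)
  # grids too small to pair
  expect_error(riskTaskConfig(probs = 0.5), "grids")
})

test_that("dominance checker resolves the published catch example", {
  # (30%, 5000) vs (50%, 5000): option B dominates
  expect_identical(dominantOption(0.3, 5000, 0.5, 5000), "B")
  expect_identical(dominantOption(0.5, 5000, 0.3, 5000), "A")
  expect_true(is.na(dominantOption(0.5, 5000, 0.5, 5000)))
  expect_true(is.na(dominantOption(0.9, 1000, 0.3, 8000)))
})

test_that("simulated choice frequencies match the analytic probability", {
  one <- data.frame(session = 1L, trial_index = 1L, p_a = 0.4, x_a = 6000,
                    p_b = 0.8, x_b = 2500, is_catch = FALSE,
                    choice = NA_character_, rt_s = NA_real_)
  many <- one[rep(1, 10000), ]
  many$trial_index <- seq_len(nrow(many))
  sch <- new("TaskSchedule", trials = many, nSessions = 1L)
  pars <- riskPreferenceParams(0.7, 0.9, 6)
  obs <- simulateAgent(sch, pars, seed = 21, noneRate = 0)
  pHat <- mean(obs$choice == "A")
  pTrue <- choiceProbability(0.4, 6000, 0.8, 2500, pars, 6000)
  expect_lt(abs(pHat - pTrue), 0.02)
  # bit-exact reproducibility under the seed
  expect_identical(simulateAgent(sch, pars, seed = 21, noneRate = 0), obs)
  # near-deterministic value maximizer picks the higher-EV option
  schEv <- buildTaskSchedule(seed = 22)
  ev <- trials(schEv)
  obsEv <- simulateAgent(schEv, riskPreferenceParams(1, 1, 1e5), seed = 23,
                         lapseRate = 0, noneRate = 0)
  main <- !ev$is_catch
  evA <- ev$p_a[main] * ev$x_a[main]
  evB <- ev$p_b[main] * ev$x_b[main]
  chosenA <- obsEv$choice[main] == "A"
  expect_true(all(chosenA == (evA > evB) | abs(evA - evB) < 1e-9))
})

test_that("MLE recovers generating parameters of a risk-neutral agent", {
  sch <- buildTaskSchedule(seed = 31)
  true <- riskPreferenceParams(1, 1, 10)
  rec <- vapply(1:6, function(i) {
    obs <- simulateAgent(sch, true, seed = 100 + i)
    riskParams(fitRiskModel(obs))[c("lambda", "gamma")]
  }, numeric(2))
  expect_gt(median(rec["lambda", ]), 0.8)
  expect_lt(median(rec["lambda", ]), 1.2)
  expect_gt(median(rec["gamma", ]), 0.8)
  expect_lt(median(rec["gamma", ]), 1.2)
})

test_that("recovery error shrinks as trials per subject increase", {
  truths <- list(c(0.4, 1, 8), c(0.8, 0.8, 8), c(1.4, 1.2, 8),
                 c(0.6, 1, 8), c(1, 1, 8))
  err <- vapply(c(120, 1200, 12000), function(nMain) {
    cfg <- riskTaskConfig(nMain = nMain)
    e <- vapply(seq_along(truths), function(k) {
      tp <- truths[[k]]
      sch <- buildTaskSchedule(cfg, seed = 40 + k)
      obs <- simulateAgent(sch, riskPreferenceParams(tp[1], tp[2], tp[3]),
                           seed = 50 + k)
      abs(riskParams(fitRiskModel(obs))[["lambda"]] - tp[1])
    }, numeric(1))
    median(e)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("degenerate and underpowered inputs are flagged, not silently fit", {
  sch <- buildTaskSchedule(seed = 61)
  stubborn <- trials(sch)
  stubborn$choice <- "A"           # always option A, value-blind
  fit <- suppressWarnings(fitRiskModel(stubborn))
  # the likelihood of a value-blind responder is essentially flat (its
  # optimum sits within ~0.2 nats of pure guessing), so the subject is
  # flagged either by the optimizer or by the catch-trial attention QC
  flagged <- fit@boundary || !fit@converged ||
    catchAccuracy(fit) < 0.75
  expect_true(flagged)
  expect_gt(fit@nll, 120 * log(2) - 1)
  few <- makeTrials(10)
  expect_error(fitRiskModel(few), "usable trials")
  # catch accuracy reported as QC
  obs <- simulateAgent(sch, riskPreferenceParams(1, 1, 10), seed = 62,
                       lapseRate = 0, noneRate = 0)
  expect_equal(catchAccuracy(fitRiskModel(obs, nStarts = 4)), 1)
})
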