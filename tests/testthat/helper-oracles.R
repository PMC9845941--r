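# Independent oracles and small fixture builders shared across tests.

# brute-force negative log-likelihood: plain per-trial formulas, no
# shared code with the package's vectorized likelihood
oracleNll <- function(trials, params, xScale) {
  lam <- params[["lambda"]]; gam <- params[["gamma"]]
  tau <- params[["tau"]]
  total <- 0
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    if (tr$is_catch || !(tr$choice %in% c("A", "B"))) next
    sv <- function(p, x) exp(-((-log(p))^gam)) * (x / xScale)^lam
    pa <- 1 / (1 + exp(-tau * (sv(tr$p_a, tr$x_a) - sv(tr$p_b, tr$x_b))))
    total <- total - log(if (tr$choice == "A") pa else 1 - pa)
  }
  total
}

# brute-force Mann-Whitney U by pair counting: #{x > y} + 0.5 #{x = y}
oracleU <- function(x, y) {
  ux <- 0
  for (xi in x) for (yi in y) ux <- ux + (xi > yi) + 0.5 * (xi == yi)
  min(ux, length(x) * length(y) - ux)
}

# exact null distribution of Ux by enumerating all rank assignments
oracleUNull <- function(n1, n2) {
  r <- seq_len(n1 + n2)
  apply(utils::combn(n1 + n2, n1), 2,
        function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
}

# exact two-sided p from the enumerated null
oracleUPvalue <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  ux <- sum(rank(c(x, y))[seq_len(n1)]) - n1 * (n1 + 1) / 2
  null <- oracleUNull(n1, n2)
  min(1, 2 * min(mean(null <= ux), mean(null >= ux)))
}

# hand-built trial table for likelihood tests
makeTrials <- function(n, seed = 1) {
  withr::with_seed(seed, {
    data.frame(
      session = 1L, trial_index = seq_len(n),
      p_a = sample(seq(0.1, 0.9, 0.1), n, TRUE),
      x_a = sample(seq(500, 10000, 500), n, TRUE),
      p_b = sample(seq(0.1, 0.9, 0.1), n, TRUE),
      x_b = sample(seq(500, 10000, 500), n, TRUE),
      is_catch = FALSE,
      choice = sample(c("A", "B"), n, TRUE),
      rt_s = 1)
  })
}

# small synthetic recording: supplied channel series, standard events
makeRecording <- function(series, dt = 0.1,
                          events = data.frame(
                            type = c("pre_baseline", "emotional", "control",
                                     "nonemotional", "post_baseline"),
                            onset_s = c(0, 30, 78, 108, 156),
                            offset_s = c(30, 78, 108, 156, 186)),
                          subjectId = "T01") {
  FnirsRecording(series, dt, events, subjectId)
}

# truth row sufficient for the per-subject generators
makeTruthRow <- function(subject_id = "S001", group = "abstainer",
                         contrast = 30, vft = 20, p_fa = 0.05,
                         p_om = 0.05, rtE = 700, rtN = 600) {
  data.frame(subject_id = subject_id, group = group,
             lambda = 0.5, gamma = 1, tau = 8,
             contrast_right_frontotemporal = contrast,
             contrast_frontopolar = contrast,
             contrast_left_frontotemporal = contrast,
             vft_frontopolar = vft, vft_left_frontotemporal = vft,
             vft_right_frontotemporal = vft,
             p_fa = p_fa, p_om = p_om,
             rt_med_emotional = rtE, rt_med_nonemotional = rtN,
             nback_acc1 = 0.95, nback_acc2 = 0.85,
             nback_rt1 = 550, nback_rt2 = 650,
             vft_mean = 14.5, cardiac_freq = 1.1)
}
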