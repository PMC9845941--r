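## Prospect-theory model of two-option risky choice:
##   w(p) = exp(-(-ln p)^gamma)        (one-parameter Prelec weighting)
##   u(x) = (x / xScale)^lambda        (power utility, normalized scale)
##   SV   = w(p) * u(x)
##   P(A) = logistic(tau * (SV_A - SV_B))
## lambda = 1 / <1 / >1 is risk-neutral / averse / seeking;
## gamma  = 1 is veridical probability weighting (fixed point at 1/e).

#' Prelec one-parameter probability weighting
#'
#' `w(p) = exp(-(-log(p))^gamma)`. At `gamma = 1` the weighting is the
#' identity; for every `gamma > 0` the function has a fixed point at
#' `1/e` and maps `(0, 1]` onto `(0, 1]` monotonically. `gamma < 1`
#' overweights small and underweights large probabilities.
#'
#' @param p objective probability (vectorized), in `(0, 1]`.
#' @param gamma weighting parameter, `> 0`.
#' @return weighted probability, same length as `p`.
#' @examples
#' prelecWeight(0.5, 1)      # identity: 0.5
#' prelecWeight(exp(-1), 3)  # fixed point: 1/e
#' @export
prelecWeight <- function(p, gamma) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("'p' must be numeric in (0, 1]")
  if (!is.numeric(gamma) || any(!is.finite(gamma)) || any(gamma <= 0))
    stop("'gamma' must be numeric > 0")
  exp(-((-log(p))^gamma))
}

#' Power utility of a reward magnitude
#'
#' `u(x) = (x / xScale)^lambda`, the utility-sensitivity form whose
#' curvature parameter reads risk-averse (`lambda < 1`), risk-neutral
#' (`lambda = 1`) or risk-seeking (`lambda > 1`). Magnitudes are
#' normalized by `xScale` (largest magnitude on offer) so the softmax
#' temperature is comparable across schedules.
#'
#' @param x reward magnitude in JPY (vectorized), `> 0`.
#' @param lambda utility sensitivity, `> 0`.
#' @param xScale normalization magnitude in JPY, `> 0`.
#' @return utility, `> 0`.
#' @export
utilityPower <- function(x, lambda, xScale) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'x' must be numeric > 0")
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be numeric > 0")
  if (!is.numeric(xScale) || any(!is.finite(xScale)) || any(xScale <= 0))
    stop("'xScale' must be numeric > 0")
  (x / xScale)^lambda
}

#' Subjective value of a gamble option
#'
#' Composition `w(p; gamma) * u(x; lambda)`; at `lambda = gamma = 1` this
#' is the scaled expected value `p * x / xScale`.
#'
#' @inheritParams prelecWeight
#' @inheritParams utilityPower
#' @return subjective value, `> 0`.
#' @export
subjectiveValue <- function(p, x, lambda, gamma, xScale) {
  prelecWeight(p, gamma) * utilityPower(x, lambda, xScale)
}

#' Softmax probability of choosing option A
#'
#' `P(A) = 1 / (1 + exp(-tau * (SV_A - SV_B)))`: equals 0.5 when the two
#' subjective values tie and sharpens with the inverse temperature
#' `tau`.
#'
#' @param pA,xA,pB,xB probabilities and magnitudes of options A and B
#'   (vectorized over trials).
#' @param params named numeric vector with `lambda`, `gamma`, `tau`
#'   (see [riskPreferenceParams()]).
#' @param xScale utility normalization magnitude.
#' @param log.p return log probability.
#' @return probability of choosing A, in `(0, 1)`.
#' @export
choiceProbability <- function(pA, xA, pB, xB, params, xScale,
                              log.p = FALSE) {
  params <- riskPreferenceParams(params["lambda"], params["gamma"],
                                 params["tau"])
  d <- subjectiveValue(pA, xA, params[["lambda"]], params[["gamma"]],
                       xScale) -
       subjectiveValue(pB, xB, params[["lambda"]], params[["gamma"]],
                       xScale)
  unname(stats::plogis(params[["tau"]] * d, log.p = log.p))
}

#' Validate a risk-preference parameter vector
#'
#' @param lambda,gamma,tau strictly positive finite scalars (utility
#'   sensitivity, Prelec weighting, softmax inverse temperature).
#' @return named numeric vector `c(lambda, gamma, tau)`.
#' @export
riskPreferenceParams <- function(lambda, gamma, tau) {
  out <- c(lambda = unname(lambda), gamma = unname(gamma),
           tau = unname(tau))
  if (any(!is.finite(out)) || any(out <= 0))
    stop("lambda, gamma and tau must all be strictly positive and finite")
  out
}

.usableTrials <- function(trials) {
  !trials$is_catch & trials$choice %in% c("A", "B")
}

#' Negative log-likelihood of observed gamble choices
#'
#' Sums `-log P(observed choice)` over usable trials. Catch trials
#' (attention checks with a dominant option) and no-response trials are
#' excluded: they probe attention, not preference.
#'
#' @param trials data.frame with columns `p_a`, `x_a`, `p_b`, `x_b`,
#'   `is_catch`, `choice` (`"A"`, `"B"` or `"none"`).
#' @param params named vector `lambda`/`gamma`/`tau`.
#' @param xScale utility normalization magnitude; defaults to the
#'   largest magnitude in `trials`.
#' @return negative log-likelihood in nats (`>= 0`).
#' @export
negLogLik <- function(trials, params, xScale = max(trials$x_a, trials$x_b)) {
  use <- .usableTrials(trials)
  if (!any(use)) stop("no usable (non-catch, responded) trials")
  tr <- trials[use, , drop = FALSE]
  lpA <- choiceProbability(tr$p_a, tr$x_a, tr$p_b, tr$x_b, params, xScale,
                           log.p = TRUE)
  lpB <- choiceProbability(tr$p_b, tr$x_b, tr$p_a, tr$x_a, params, xScale,
                           log.p = TRUE)
  ll <- ifelse(tr$choice == "A", lpA, lpB)
  if (any(is.na(ll))) stop("NaN in per-trial choice probability")
  -sum(ll)
}

## Halton low-discrepancy sequence; deterministic multi-start lattice.
.halton <- function(n, base) {
  vapply(seq_len(n), function(i) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }, numeric(1))
}

#' Fit the risk-preference model by multi-start maximum likelihood
#'
#' Bounded maximum-likelihood estimation of `(lambda, gamma, tau)` from
#' one subject's gamble choices. The likelihood is multi-modal in
#' `(gamma, tau)`, so the optimizer (L-BFGS-B on the log-parameter
#' scale) is restarted from `nStarts` points of a deterministic Halton
#' lattice spread log-uniformly over the bound box; the best local
#' optimum wins. `tau` is a nuisance parameter and is never compared
#' between groups.
#'
#' @inheritParams negLogLik
#' @param nStarts number of optimization starts.
#' @param bounds list of length-2 numeric ranges for `lambda`, `gamma`,
#'   `tau`.
#' @param minTrials minimum number of usable trials required.
#' @return A [RiskModelFit-class] object.
#' @examples
#' sched <- buildTaskSchedule(seed = 1)
#' obs <- simulateAgent(sched, riskPreferenceParams(0.7, 1, 10), seed = 2)
#' fitRiskModel(obs, nStarts = 5)
#' @export
fitRiskModel <- function(trials, nStarts = 20,
                         bounds = list(lambda = c(0.05, 5),
                                       gamma = c(0.05, 5),
                                       tau = c(0.01, 100)),
                         minTrials = 30,
                         xScale = max(trials$x_a, trials$x_b)) {
  use <- .usableTrials(trials)
  if (sum(use) < minTrials)
    stop("need at least ", minTrials, " usable trials, got ", sum(use))
  lo <- log(c(bounds$lambda[1], bounds$gamma[1], bounds$tau[1]))
  hi <- log(c(bounds$lambda[2], bounds$gamma[2], bounds$tau[2]))
  ## precompute trial vectors once; objective works on log-parameters
  tr <- trials[use, , drop = FALSE]
  chooseA <- tr$choice == "A"
  lq <- -log(tr$p_a)   # -ln p, > 0 on (0,1); exactly 0 at p = 1
  lqB <- -log(tr$p_b)
  uA <- log(tr$x_a / xScale)
  uB <- log(tr$x_b / xScale)
  sgn <- ifelse(chooseA, 1, -1)
  obj <- function(lp) {
    lambda <- exp(lp[1]); gamma <- exp(lp[2]); tau <- exp(lp[3])
    d <- exp(-(lq^gamma) + lambda * uA) - exp(-(lqB^gamma) + lambda * uB)
    v <- -sum(stats::plogis(sgn * tau * d, log.p = TRUE))
    if (!is.finite(v)) .Machine$double.xmax else v
  }
  f <- cbind(.halton(nStarts, 2), .halton(nStarts, 3), .halton(nStarts, 5))
  best <- NULL
  bestIdx <- NA_integer_
  for (i in seq_len(nStarts)) {
    start <- lo + f[i, ] * (hi - lo)
    res <- tryCatch(
      stats::optim(start, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 100, factr = 1e8)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      bestIdx <- i
    }
  }
  if (is.null(best))
    stop("all optimization starts failed")
  par <- exp(best$par)
  names(par) <- c("lambda", "gamma", "tau")
  atBound <- any(best$par <= lo + 1e-6) || any(best$par >= hi - 1e-6)
  ## catch-trial accuracy QC
  ct <- trials[trials$is_catch & trials$choice %in% c("A", "B"), ,
               drop = FALSE]
  acc <- if (nrow(ct)) {
    dom <- dominantOption(ct$p_a, ct$x_a, ct$p_b, ct$x_b)
    mean(ct$choice == dom)
  } else NA_real_
  conv <- best$convergence == 0
  if (!conv)
    warning("best start did not converge; parameters reported as-is")
  new("RiskModelFit", params = par, nll = best$value,
      nTrialsUsed = sum(use), converged = conv, boundary = atBound,
      nStarts = as.integer(nStarts), bestStart = bestIdx,
      catchAccuracy = acc)
}

#' Which option dominates, if any
#'
#' Option A dominates B when it is at least as good in both probability
#' and magnitude and strictly better in one; identical options have no
#' dominant member.
#'
#' @param pA,xA,pB,xB option attributes (vectorized).
#' @return `"A"`, `"B"` or `NA` per pair.
#' @export
dominantOption <- function(pA, xA, pB, xB) {
  a <- (pA >= pB & xA >= xB) & (pA > pB | xA > xB)
  b <- (pB >= pA & xB >= xA) & (pB > pA | xB > xA)
  ifelse(a, "A", ifelse(b, "B", NA_character_))
}

#' Risk-task configuration
#'
#' Option grids and counts for [buildTaskSchedule()]. Defaults mirror
#' the study design: 120 main trials in 3 sessions with one catch trial
#' inserted after a randomly selected trial in every block of 15 main
#' trials (8 catches in total). The option set itself is not printed in
#' the study, so probabilities run over 10-90% and magnitudes over
#' 500-10,000 JPY.
#'
#' @param probs probability grid.
#' @param mags magnitude grid (JPY).
#' @param nMain number of main trials.
#' @param nSessions number of sessions.
#' @param catchBlock insert one catch per this many main trials.
#' @return list of class `riskTaskConfig`.
#' @export
riskTaskConfig <- function(probs = seq(0.1, 0.9, by = 0.1),
                           mags = seq(500, 10000, by = 500),
                           nMain = 120, nSessions = 3, catchBlock = 15) {
  if (length(probs) < 2 || length(mags) < 2)
    stop("probability and magnitude grids need at least 2 values each ",
         "to build non-dominated pairs")
  if (nMain %% nSessions != 0 || nMain %% catchBlock != 0)
    stop("nMain must be divisible by nSessions and catchBlock")
  structure(list(probs = probs, mags = mags, nMain = nMain,
                 nSessions = nSessions, catchBlock = catchBlock),
            class = "riskTaskConfig")
}

#' Build a risk-task trial schedule
#'
#' Main trials pair two non-dominated options (the higher-probability
#' option always carries the lower magnitude, so neither option wins on
#' both attributes); catch trials share a magnitude and differ only in
#' probability, e.g. (30%, 5000) vs (50%, 5000), so one option is
#' objectively correct.
#'
#' @param config a [riskTaskConfig()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [TaskSchedule-class].
#' @export
buildTaskSchedule <- function(config = riskTaskConfig(), seed = NULL) {
  .withSeed(seed, {
    nMain <- config$nMain
    perSession <- nMain / config$nSessions
    drawMain <- function(n) {
      p <- t(replicate(n, sort(sample(config$probs, 2))))    # pLow, pHigh
      m <- t(replicate(n, sort(sample(config$mags, 2))))     # mLow, mHigh
      ## higher probability gets lower magnitude -> non-dominated
      aHigh <- sample(c(TRUE, FALSE), n, replace = TRUE)
      data.frame(
        p_a = ifelse(aHigh, p[, 2], p[, 1]),
        x_a = ifelse(aHigh, m[, 1], m[, 2]),
        p_b = ifelse(aHigh, p[, 1], p[, 2]),
        x_b = ifelse(aHigh, m[, 2], m[, 1]),
        is_catch = FALSE)
    }
    drawCatch <- function(n) {
      p <- t(replicate(n, sort(sample(config$probs, 2))))
      m <- sample(config$mags, n, replace = TRUE)
      aHigh <- sample(c(TRUE, FALSE), n, replace = TRUE)
      data.frame(
        p_a = ifelse(aHigh, p[, 2], p[, 1]), x_a = m,
        p_b = ifelse(aHigh, p[, 1], p[, 2]), x_b = m,
        is_catch = TRUE)
    }
    main <- drawMain(nMain)
    nCatch <- nMain / config$catchBlock
    catch <- drawCatch(nCatch)
    ## position of the catch inside each block of catchBlock main trials
    slot <- sample.int(config$catchBlock, nCatch, replace = TRUE)
    ord <- list()
    ci <- 1L
    for (b in seq_len(nCatch)) {
      idx <- ((b - 1) * config$catchBlock + 1):(b * config$catchBlock)
      blk <- main[idx, , drop = FALSE]
      blk$main_index <- idx
      cat_row <- catch[b, , drop = FALSE]
      cat_row$main_index <- NA_integer_
      ord[[length(ord) + 1L]] <- rbind(
        blk[seq_len(slot[b]), ], cat_row,
        if (slot[b] < config$catchBlock)
          blk[(slot[b] + 1):config$catchBlock, ])
      ci <- ci + 1L
    }
    tr <- do.call(rbind, ord)
    ## session follows the running count of main trials
    mainCount <- cumsum(!tr$is_catch)
    tr$session <- as.integer(pmin(ceiling(pmax(mainCount, 1) / perSession),
                                  config$nSessions))
    tr$trial_index <- seq_len(nrow(tr))
    tr$choice <- NA_character_
    tr$rt_s <- NA_real_
    tr$main_index <- NULL
    rownames(tr) <- NULL
    new("TaskSchedule",
        trials = tr[, c("session", "trial_index", "p_a", "x_a", "p_b",
                        "x_b", "is_catch", "choice", "rt_s")],
        nSessions = as.integer(config$nSessions))
  })
}

#' Simulate an agent performing the risk task
#'
#' Generative counterpart of the likelihood: on main trials the choice
#' is Bernoulli with the softmax [choiceProbability()]; on catch trials
#' the dominant option is chosen with probability `1 - lapseRate`. With
#' probability `noneRate` a trial times out (`choice = "none"`).
#'
#' @param schedule a [TaskSchedule-class].
#' @param params named vector `lambda`/`gamma`/`tau`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param lapseRate probability of missing a catch trial.
#' @param noneRate probability of a response timeout.
#' @param xScale utility normalization; defaults to the schedule's
#'   largest magnitude.
#' @return the schedule's trial data.frame with `choice` and `rt_s`
#'   filled in.
#' @export
simulateAgent <- function(schedule, params, seed = NULL, lapseRate = 0.02,
                          noneRate = 0.01, xScale = NULL) {
  tr <- trials(schedule)
  if (is.null(xScale)) xScale <- max(tr$x_a, tr$x_b)
  .withSeed(seed, {
    pA <- choiceProbability(tr$p_a, tr$x_a, tr$p_b, tr$x_b, params, xScale)
    chooseA <- stats::rbinom(nrow(tr), 1, pA) == 1
    dom <- dominantOption(tr$p_a, tr$x_a, tr$p_b, tr$x_b)
    lapse <- stats::runif(nrow(tr)) < lapseRate
    isC <- tr$is_catch
    chooseA[isC] <- ifelse(lapse[isC], dom[isC] != "A", dom[isC] == "A")
    tr$choice <- ifelse(chooseA, "A", "B")
    tr$rt_s <- pmin(stats::rlnorm(nrow(tr), log(1.2), 0.25), 2.99)
    none <- stats::runif(nrow(tr)) < noneRate
    tr$choice[none] <- "none"
    tr$rt_s[none] <- NA_real_
    tr
  })
}

## run expr under a temporary seed (NULL = inherit current RNG state)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
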