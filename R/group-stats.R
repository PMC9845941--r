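## Group comparisons (Mann-Whitney U / Student's t / chi-squared),
## Spearman correlations, and the standardized binomial logistic
## prognosis model with its Box-Tidwell linearity check. No
## multiple-testing correction is applied anywhere: every p-value is
## reported raw, matching the single-comparison reporting style of the
## analysis this package reproduces.

#' Mann-Whitney U test
#'
#' Rank-based two-sample test. U is computed from the rank sums (with
#' average ranks under ties) and reported as `min(Ux, Uy)`; the p-value
#' is exact when the combined sample size is at most 20 and the data
#' are tie-free, and otherwise uses the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y numeric samples.
#' @return list: `U`, `Ux`, `Uy`, `p.value`, `method`.
#' @export
mannWhitneyU <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  Ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Uy <- n1 * n2 - Ux
  ties <- anyDuplicated(c(x, y)) > 0
  if (stats::sd(c(x, y)) == 0) {
    warning("all values identical across both groups; p set to 1")
    return(list(U = min(Ux, Uy), Ux = Ux, Uy = Uy, p.value = 1,
                method = "degenerate"))
  }
  exact <- (n1 + n2) <= 20 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  list(U = min(Ux, Uy), Ux = Ux, Uy = Uy, p.value = p,
       method = if (exact) "exact" else "normal approximation")
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the p-value from the
#' t-approximation on `n - 2` degrees of freedom.
#'
#' @param x,y paired numeric vectors, `n >= 4`.
#' @return list: `rho`, `p.value`, `n`; `rho` is `NA` (with a warning)
#'   for constant input.
#' @export
spearmanRho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman rho undefined")
    return(list(rho = NA_real_, p.value = NA_real_, n = n))
  }
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), n - 2)
  }
  list(rho = rho, p.value = p, n = n)
}

#' Column standardization with a reusable transform
#'
#' z-scores every column (mean 0, SD 1, denominator `n - 1`) and stores
#' the centers and scales so the same transform can be reapplied or
#' inverted.
#'
#' @param X numeric matrix or data.frame.
#' @return list of class `standardizer`: `z` (matrix), `center`,
#'   `scale`.
#' @export
standardizeColumns <- function(X) {
  X <- as.matrix(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(X)[sds == 0 | !is.finite(sds)]
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  ctr <- colMeans(X)
  z <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  structure(list(z = z, center = ctr, scale = sds),
            class = "standardizer")
}

#' @describeIn standardizeColumns apply a stored transform to new data
#' @param s a `standardizer`.
#' @param newX data on the original scale.
#' @export
applyStandardizer <- function(s, newX) {
  sweep(sweep(as.matrix(newX), 2, s$center), 2, s$scale, "/")
}

#' @describeIn standardizeColumns invert the transform
#' @param z data on the standardized scale.
#' @export
invertStandardizer <- function(s, z) {
  sweep(sweep(as.matrix(z), 2, s$scale, "*"), 2, s$center, "+")
}

#' Box-Tidwell linearity-in-the-logit check
#'
#' Augments the logistic model with `x * log(x)` interaction terms
#' (after shifting each predictor to be strictly positive where needed)
#' and reports the Wald p-value of each interaction; all p > 0.05 reads
#' as "linear". Quasi-separation in the augmented model flags the
#' verdict as undetermined.
#'
#' @param X data.frame or matrix of predictors.
#' @param y binary outcome (0/1 or logical).
#' @return list: `p` (named per-predictor interaction p-values),
#'   `linear` (logical or `NA`), `verdict` (character), `flagged`.
#' @export
boxTidwellCheck <- function(X, y) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  shifted <- lapply(X, function(v) if (min(v) <= 0) v + 1 - min(v) else v)
  dat <- as.data.frame(shifted)
  nm <- names(dat)
  inter <- paste0("bt_", nm)
  for (i in seq_along(nm)) dat[[inter[i]]] <- dat[[nm[i]]] * log(dat[[nm[i]]])
  dat$.y <- y
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  p <- stats::setNames(rep(NA_real_, length(nm)), nm)
  hit <- intersect(inter, rownames(co))
  p[match(hit, inter)] <- co[hit, "Pr(>|z|)"]
  flagged <- sepWarn || !fit$converged || any(is.na(p))
  linear <- if (flagged) NA else all(p > 0.05)
  verdict <- if (flagged) "undetermined (separation in augmented model)"
             else if (linear) "all interaction terms linear (all p > 0.05)"
             else "non-linearity detected"
  list(p = p, linear = linear, verdict = verdict, flagged = flagged)
}

#' Standardized binomial logistic prognosis model
#'
#' Maximum-likelihood logistic regression of a binary relapse indicator
#' on standardized predictors. Reports per-predictor standardized
#' coefficients, odds ratios with Wald 95% CIs and p-values, plus
#' in-sample sensitivity and specificity at a predicted-probability
#' cutoff of 0.5 with relapse as the positive class.
#'
#' @param X data.frame or matrix of predictors (original scale; they
#'   are standardized internally and the transform is returned).
#' @param y binary outcome, 1 = relapse.
#' @param cutoff classification cutoff on the predicted probability.
#' @return list: `coefficients` (data.frame with `term`, `estimate`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `p.value`), `sensitivity`,
#'   `specificity`, `confusion` (TP/FN/TN/FP), `standardizer`,
#'   `separation` (logical), `fit` (the `glm` object).
#' @export
logisticPrognosis <- function(X, y, cutoff = 0.5) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("outcome must contain both classes")
  X <- as.data.frame(X)
  if (nrow(X) <= ncol(X)) stop("need more subjects than predictors")
  s <- standardizeColumns(X)
  dat <- as.data.frame(s$z)
  dat$.y <- y
  sepWarn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  terms <- setdiff(rownames(co), "(Intercept)")
  est <- co[terms, "Estimate"]
  se <- co[terms, "Std. Error"]
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = terms,
    estimate = est,
    odds_ratio = exp(est),
    ci_low = exp(est - zq * se),
    ci_high = exp(est + zq * se),
    p.value = co[terms, "Pr(>|z|)"],
    row.names = NULL)
  pred <- stats::fitted(fit) >= cutoff
  tp <- sum(pred & y == 1); fn <- sum(!pred & y == 1)
  tn <- sum(!pred & y == 0); fp <- sum(pred & y == 0)
  list(coefficients = coefs,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       confusion = c(TP = tp, FN = fn, TN = tn, FP = fp),
       standardizer = s,
       separation = sepWarn,
       fit = fit)
}

#' Sensitivity and specificity from a confusion matrix
#'
#' @param confusion named numeric with `TP`, `FN`, `TN`, `FP`.
#' @return named numeric `sensitivity`, `specificity` (fractions).
#' @export
confusionStats <- function(confusion) {
  c(sensitivity = unname(confusion["TP"] /
                           (confusion["TP"] + confusion["FN"])),
    specificity = unname(confusion["TN"] /
                           (confusion["TN"] + confusion["FP"])))
}

## summary-style -> test assignment (median+IQR style variables get U,
## mean+-SD style get t, counts get chi-squared)
.defaultTestMap <- c(
  age = "t", daily_alcohol_g = "t", arrs_sv = "t", bis11 = "t", audit = "t",
  age_first_drink = "u", age_onset = "u", duration_illness = "u",
  drinking_days = "u", hand = "u", education_years = "u", sighd = "u",
  bdi = "u", sex = "chisq", comorbid = "chisq",
  false_alarm_emotional = "u", omission_emotional = "u",
  rt_emotional_ms = "u", rt_nonemotional_ms = "u", vft_words = "u",
  nback1_percent_correct = "u", nback1_rt_ms = "u",
  nback2_percent_correct = "u", nback2_rt_ms = "u",
  lambda = "u", gamma = "u",
  contrast_frontopolar = "u", contrast_left_frontotemporal = "u",
  contrast_right_frontotemporal = "u",
  vft_frontopolar = "u", vft_left_frontotemporal = "u",
  vft_right_frontotemporal = "u")

.summarizeVar <- function(v, style) {
  v <- v[!is.na(v)]
  if (style == "t")
    sprintf("%.1f +/- %.1f", mean(v), stats::sd(v))
  else
    sprintf("%.2f (%.2f-%.2f)", stats::median(v),
            stats::quantile(v, 0.25), stats::quantile(v, 0.75))
}

#' Compare variables between prognosis groups
#'
#' Runs the per-variable two-group test (Mann-Whitney U for variables
#' summarized as median + IQR, Student's t for mean +/- SD variables,
#' chi-squared for categorical counts) and formats group summaries in
#' the matching style.
#'
#' @param df data.frame with a `group` column (`abstainer`/`relapser`).
#' @param vars variable names to compare.
#' @param testMap named character vector assigning `"u"`, `"t"` or
#'   `"chisq"` per variable (defaults cover the standard cohort table).
#' @return data.frame: `variable`, `test`, `statistic`, `p.value`,
#'   `abstainers`, `relapsers`.
#' @export
compareGroups <- function(df, vars, testMap = .defaultTestMap) {
  stopifnot("group" %in% names(df))
  a <- df$group == "abstainer"
  out <- lapply(vars, function(v) {
    if (!v %in% names(df) || all(is.na(df[[v]]))) return(NULL)
    type <- if (v %in% names(testMap)) testMap[[v]] else "u"
    x <- df[[v]][a]; y <- df[[v]][!a]
    if (type == "chisq") {
      tab <- table(factor(df$group, c("abstainer", "relapser")), df[[v]])
      ct <- suppressWarnings(stats::chisq.test(tab))
      data.frame(variable = v, test = "chi_squared",
                 statistic = unname(ct$statistic), p.value = ct$p.value,
                 abstainers = paste(tab[1, ], collapse = "/"),
                 relapsers = paste(tab[2, ], collapse = "/"))
    } else if (type == "t") {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      data.frame(variable = v, test = "student_t",
                 statistic = unname(tt$statistic), p.value = tt$p.value,
                 abstainers = .summarizeVar(x, "t"),
                 relapsers = .summarizeVar(y, "t"))
    } else {
      mw <- mannWhitneyU(x[!is.na(x)], y[!is.na(y)])
      data.frame(variable = v, test = "mann_whitney_u",
                 statistic = mw$U, p.value = mw$p.value,
                 abstainers = .summarizeVar(x, "u"),
                 relapsers = .summarizeVar(y, "u"))
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full group-level analysis of a subject summary table
#'
#' Reproduces the report structure of the study: demographic and
#' clinical comparison, behavioral comparison, per-region
#' emotional-minus-neutral contrasts, risk-model parameter comparison,
#' the contrast-vs-craving Spearman correlation per group, and the
#' standardized logistic prognosis model (with Box-Tidwell check,
#' odds ratios and in-sample classification metrics). Variables absent
#' from the table are skipped and listed in `skipped`.
#'
#' @param summaryDf one row per subject: `subject_id`, `group`,
#'   covariates, behavioral summaries, `lambda`, `gamma`, region
#'   contrasts.
#' @param logisticPredictors predictor columns of the prognosis model.
#' @return list of class `groupAnalysis`: `demographics`, `behavior`,
#'   `fnirs`, `risk`, `correlations`, `logistic`, `boxTidwell`,
#'   `skipped`.
#' @export
runGroupAnalysis <- function(summaryDf,
                             logisticPredictors =
                               c("contrast_right_frontotemporal", "lambda",
                                 "age_onset", "audit", "arrs_sv", "age")) {
  present <- function(v) v[v %in% names(summaryDf) &
                             vapply(v, function(x)
                               x %in% names(summaryDf) &&
                                 !all(is.na(summaryDf[[x]])), logical(1))]
  demo <- c("age", "sex", "age_first_drink", "age_onset",
            "duration_illness", "drinking_days", "daily_alcohol_g", "hand",
            "education_years", "sighd", "bdi", "arrs_sv", "bis11", "audit",
            "comorbid")
  behav <- c("false_alarm_emotional", "omission_emotional",
             "rt_emotional_ms", "rt_nonemotional_ms", "vft_words",
             "nback1_percent_correct", "nback1_rt_ms",
             "nback2_percent_correct", "nback2_rt_ms")
  fnirs <- c("contrast_frontopolar", "contrast_left_frontotemporal",
             "contrast_right_frontotemporal", "vft_frontopolar",
             "vft_left_frontotemporal", "vft_right_frontotemporal")
  risk <- c("lambda", "gamma")
  skipped <- setdiff(c(demo, behav, fnirs, risk),
                     c(present(demo), present(behav), present(fnirs),
                       present(risk)))
  ## contrast-vs-craving correlation per group
  correl <- NULL
  if (all(c("contrast_right_frontotemporal", "arrs_sv") %in%
            names(summaryDf))) {
    correl <- do.call(rbind, lapply(c("abstainer", "relapser"), function(g) {
      d <- summaryDf[summaryDf$group == g, ]
      sp <- spearmanRho(d$contrast_right_frontotemporal, d$arrs_sv)
      data.frame(group = g, rho = sp$rho, p.value = sp$p.value, n = sp$n)
    }))
  }
  logit <- NULL; bt <- NULL
  preds <- present(logisticPredictors)
  if (length(preds) >= 2 &&
      length(unique(summaryDf$group)) == 2) {
    cc <- stats::complete.cases(summaryDf[, preds])
    Xl <- summaryDf[cc, preds]
    yl <- as.integer(summaryDf$group[cc] == "relapser")
    bt <- boxTidwellCheck(Xl, yl)
    logit <- logisticPrognosis(Xl, yl)
  }
  structure(list(
    demographics = compareGroups(summaryDf, present(demo)),
    behavior = compareGroups(summaryDf, present(behav)),
    fnirs = compareGroups(summaryDf, present(fnirs)),
    risk = compareGroups(summaryDf, present(risk)),
    correlations = correl,
    logistic = logit,
    boxTidwell = bt,
    skipped = skipped), class = "groupAnalysis")
}
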