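test_that("Mann-Whitney U: exact example, identities, degenerate input", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)          # 2 / C(6,3)
  expect_identical(r$method, "exact")
  # Ux + Uy = n1 * n2 on tie-free data
  x <- c(2.2, 9.1, 4.4, 7.7); y <- c(1.1, 3.3, 8.8)
  r2 <- mannWhitneyU(x, y)
  expect_equal(r2$Ux + r2$Uy, 12)
  # identical samples land at the tie midpoint n^2 / 2
  r3 <- suppressWarnings(mannWhitneyU(rep(5, 4), rep(5, 4)))
  expect_equal(r3$Ux, 8)
  expect_equal(r3$p.value, 1)
  expect_warning(mannWhitneyU(rep(1, 3), rep(1, 3)), "identical")
  expect_error(mannWhitneyU(numeric(0), 1), "non-empty")
})

test_that("U statistic agrees with brute-force pair counting", {
  withr::with_seed(20, {
    for (i in 1:30) {
      n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
      # mix of continuous and tied integer data
      if (i %% 2) {
        x <- rnorm(n1); y <- rnorm(n2)
      } else {
        x <- sample(1:4, n1, TRUE); y <- sample(1:4, n2, TRUE)
      }
      r <- suppressWarnings(mannWhitneyU(x, y))
      expect_equal(r$U, oracleU(x, y))
    }
  })
})

test_that("exact p-values match full enumeration; null pmf sums to 1", {
  withr::with_seed(21, {
    for (i in 1:10) {
      n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
      x <- rnorm(n1); y <- rnorm(n2)
      expect_equal(mannWhitneyU(x, y)$p.value, oracleUPvalue(x, y),
                   tolerance = 1e-12)
    }
  })
  # enumerated null distribution of U is a proper pmf and matches the
  # closed-form null used for exact p-values
  for (nn in list(c(3, 3), c(4, 5))) {
    null <- oracleUNull(nn[1], nn[2])
    pmf <- table(null) / length(null)
    expect_equal(sum(pmf), 1)
    expect_equal(as.numeric(pmf),
                 stats::dwilcox(as.numeric(names(pmf)), nn[1], nn[2]))
  }
})

test_that("Spearman rho: monotone pairs, t-approximation, constants", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearmanRho(x, x^3 + 2)$rho, 1)
  expect_equal(spearmanRho(x, rev(x))$rho, -1)
  withr::with_seed(22, {
    a <- rnorm(30); b <- 0.5 * a + rnorm(30)
  })
  mine <- spearmanRho(a, b)
  ref <- stats::cor.test(a, b, method = "spearman", exact = FALSE)
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  expect_warning(r0 <- spearmanRho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r0$rho))
  expect_error(spearmanRho(1:3, 3:1), "4")
})

test_that("the generator injects the configured contrast-craving correlation", {
  cfg <- cohortConfig(nAbstainers = 250, nRelapsers = 60,
                      components = character(0))
  ch <- generateCohort(cfg, seed = 23)
  df <- merge(covariates(ch), groundTruth(ch)[, c(
    "subject_id", "contrast_right_frontotemporal")], by = "subject_id")
  ab <- df[df$group == "abstainer", ]
  rl <- df[df$group == "relapser", ]
  rhoAb <- spearmanRho(ab$contrast_right_frontotemporal, ab$arrs_sv)$rho
  rhoRl <- spearmanRho(rl$contrast_right_frontotemporal, rl$arrs_sv)$rho
  expect_lt(abs(rhoAb - (-0.439)), 0.12)   # ~2 SE at n = 250
  expect_lt(abs(rhoRl), 0.3)
})

test_that("standardization: z-scores, idempotence, invertibility", {
  s <- standardizeColumns(cbind(a = c(1, 2, 3)))
  expect_equal(s$z[, "a"], c(-1, 0, 1))
  X <- withr::with_seed(24, matrix(rnorm(40), 20, 2,
                                   dimnames = list(NULL, c("u", "v"))))
  s1 <- standardizeColumns(X)
  expect_equal(colMeans(s1$z), c(u = 0, v = 0), tolerance = 1e-12)
  expect_equal(apply(s1$z, 2, sd), c(u = 1, v = 1))
  # standardizing an already-standardized matrix changes nothing
  s2 <- standardizeColumns(s1$z)
  expect_equal(s2$z, s1$z, tolerance = 1e-12, ignore_attr = TRUE)
  # round trip
  expect_equal(invertStandardizer(s1, s1$z), X, ignore_attr = TRUE)
  expect_equal(applyStandardizer(s1, X), s1$z, ignore_attr = TRUE)
  expect_error(standardizeColumns(cbind(ok = 1:5, flat = rep(2, 5))),
               "flat")
})

test_that("Box-Tidwell check separates linear from curved logits", {
  linearOk <- vapply(1:20, function(i) {
    withr::with_seed(400 + i, {
      x <- rnorm(300)
      y <- rbinom(300, 1, plogis(0.8 * x))
    })
    all(boxTidwellCheck(data.frame(x = x), y)$p > 0.05, na.rm = TRUE)
  }, logical(1))
  expect_gte(mean(linearOk), 0.9)
  curvedCaught <- vapply(1:20, function(i) {
    withr::with_seed(500 + i, {
      x <- rnorm(2000)
      y <- rbinom(2000, 1, plogis(1.5 * x^2 - 1))
    })
    any(boxTidwellCheck(data.frame(x = x), y)$p < 0.05)
  }, logical(1))
  expect_gte(mean(curvedCaught), 0.9)
  # a linear model over several covariates reads out as linear
  withr::with_seed(26, {
    X <- data.frame(a = rnorm(400), b = rnorm(400))
    y <- rbinom(400, 1, plogis(0.5 * X$a - 0.4 * X$b))
  })
  bt <- boxTidwellCheck(X, y)
  expect_false(bt$flagged)
  expect_length(bt$p, 2)
})

test_that("logistic prognosis: classification metrics and null behavior", {
  # hand-checked confusion arithmetic: 11/5/20/3 -> 68.75% / 86.96%
  cs <- confusionStats(c(TP = 11, FN = 5, TN = 20, FP = 3))
  expect_equal(100 * cs[["sensitivity"]], 68.75)
  expect_equal(100 * cs[["specificity"]], 86.95652, tolerance = 1e-6)
  # null generator: odds ratios near 1
  withr::with_seed(27, {
    X <- data.frame(a = rnorm(2000), b = rnorm(2000))
    y <- rbinom(2000, 1, 0.4)
  })
  res <- logisticPrognosis(X, y)
  expect_true(all(abs(log(res$coefficients$odds_ratio)) < 0.15))
  expect_false(res$separation)
  # reported sensitivity/specificity recompute from the confusion matrix
  rc <- confusionStats(res$confusion)
  expect_equal(rc[["sensitivity"]], res$sensitivity)
  expect_equal(rc[["specificity"]], res$specificity)
  # Wald CI bounds are ordered and OR = exp(coefficient)
  expect_true(all(res$coefficients$ci_low < res$coefficients$ci_high))
  expect_equal(res$coefficients$odds_ratio,
               exp(res$coefficients$estimate))
  # perfect separation is flagged
  sep <- data.frame(x = c(-(10:1), 1:10))
  ysep <- rep(0:1, each = 10)
  resSep <- logisticPrognosis(sep, ysep)
  expect_true(resSep$separation)
  expect_error(logisticPrognosis(data.frame(x = 1:5), rep(1, 5)),
               "classes")
})

test_that("logistic coefficient bias shrinks along the sample-size ladder", {
  beta <- c(log(0.161), log(7.037))
  err <- vapply(c(200, 2000, 20000), function(n) {
    e <- vapply(1:5, function(r) {
      withr::with_seed(600 + 7 * r + n %% 97, {
        X <- data.frame(c1 = rnorm(n), c2 = rnorm(n))
        y <- rbinom(n, 1, plogis(qlogis(17 / 41) + beta[1] * X$c1 +
                                   beta[2] * X$c2))
      })
      fit <- logisticPrognosis(X, y)
      mean(abs(fit$coefficients$estimate - beta))
    }, numeric(1))
    median(e)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("group analysis: null cohorts stay null, structure is complete", {
  makeNullSummary <- function(seed) {
    withr::with_seed(seed, {
      n <- 41
      data.frame(
        subject_id = sprintf("S%03d", 1:n),
        group = rep(c("abstainer", "relapser"), c(24, 17)),
        sex = sample(c("male", "female"), n, TRUE, c(0.85, 0.15)),
        age = rnorm(n, 53, 9),
        age_onset = rlnorm(n, log(44), 0.3),
        audit = rnorm(n, 22, 7),
        arrs_sv = rnorm(n, 14.8, 4.4),
        lambda = rlnorm(n, log(0.35), 0.8),
        gamma = rlnorm(n, 0, 0.15),
        contrast_right_frontotemporal = rnorm(n, 0, 70),
        rt_nonemotional_ms = rlnorm(n, log(570), 0.12),
        vft_words = rpois(n, 14))
    })
  }
  ps <- unlist(lapply(1:5, function(s) {
    ga <- runGroupAnalysis(makeNullSummary(s))
    c(ga$demographics$p.value, ga$behavior$p.value, ga$fnirs$p.value,
      ga$risk$p.value)
  }))
  # with no injected effect, roughly 5% of tests reject; allow wide slack
  expect_lt(mean(ps < 0.05, na.rm = TRUE), 0.2)
  ga <- runGroupAnalysis(makeNullSummary(99))
  expect_s3_class(ga$demographics, "data.frame")
  expect_true(all(c("mann_whitney_u", "student_t", "chi_squared") %in%
                    c(ga$demographics$test)))
  expect_named(ga$correlations, c("group", "rho", "p.value", "n"))
  expect_equal(nrow(ga$logistic$coefficients), 6)
  # deterministic: same input, identical output
  expect_identical(runGroupAnalysis(makeNullSummary(99)), ga)
})
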