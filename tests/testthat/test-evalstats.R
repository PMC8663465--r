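test_that("ROC handles perfect separation, reversals, and ties", {
  r1 <- roc_auc(c(0.9, 0.8, 0.7, 0.6, 0.5), c(1, 1, 1, 0, 0))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(0.9, 0.4, 0.5, 0.1), c(1, 1, 0, 0))
  expect_equal(r2$auc, 0.75) # 3 of 4 concordant pairs
  r3 <- roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(r3$auc, 0.5)
  expect_equal(r3$youden_j, 0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "fs_config_error")
})

test_that("AUC equals brute-force concordance and reverses under negation", {
  set.seed(11)
  for (i in 1:60) {
    n <- sample(4:30, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5)) # both classes guaranteed
    scores <- round(runif(n), sample(1:3, 1)) # coarse grid provokes ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(12)
  scores <- runif(40)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(roc_auc(scores, labels)$auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("Youden threshold maximizes J and reports the straddling midpoint", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(r$youden_j, 1)
  expect_equal(r$youden_threshold, 0.6)
  # equivalence with an exhaustive midpoint sweep on random instances
  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:25, 1)
    labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
    scores <- round(runif(n), 2)
    r <- roc_auc(scores, labels)
    expect_equal(r$youden_j, oracle_youden_j(scores, labels), tolerance = 1e-12)
    # the reported threshold must realize the maximal J
    tpr <- sum(scores >= r$youden_threshold & labels == 1) / sum(labels == 1)
    fpr <- sum(scores >= r$youden_threshold & labels == 0) / sum(labels == 0)
    expect_equal(tpr - fpr, r$youden_j, tolerance = 1e-12)
    expect_gte(r$youden_j, 0)
    expect_lte(r$youden_j, 1)
  }
})

test_that("Youden J approaches 2*AUC - 1 for equal-variance binormal scores", {
  set.seed(14)
  n <- 1e5
  scores <- c(rnorm(n, 1), rnorm(n, 0))
  labels <- rep(c(1, 0), each = n)
  r <- roc_auc(round(scores, 2), labels)
  # binormal equal-variance: J = 2*Phi(d/2) - 1, AUC = Phi(d/sqrt(2))
  expect_equal(r$auc, pnorm(1 / sqrt(2)), tolerance = 0.01)
  expect_equal(r$youden_j, 2 * pnorm(0.5) - 1, tolerance = 0.015)
})

test_that("classification metrics follow confusion-matrix arithmetic", {
  m <- classification_metrics(c(1, 1, 1, 0, 0), c(1, 1, 0, 0, 0))
  expect_identical(c(m$tp, m$fp, m$fn, m$tn), c(2L, 0L, 1L, 2L))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$f_measure, 0.8)
  expect_equal(m$accuracy, 0.8)
  # perfect predictions
  expect_equal(classification_metrics(c(1, 0), c(1, 0))$accuracy, 1)
  # all-negative predictions: recall 0, precision flagged undefined
  m2 <- classification_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_false(m2$precision_defined)
  expect_true(is.na(m2$precision))
  expect_equal(m2$recall, 0)
})

test_that("Pearson correlation and Fisher-z interval match hand computation", {
  expect_equal(pearson_ci(1:3, c(2, 4, 6))$r, 1)
  expect_equal(pearson_ci(1:3, c(6, 4, 2))$r, -1)
  res <- pearson_ci(1:5, c(2, 1, 4, 3, 6))
  expect_equal(res$r, 10 / sqrt(10 * 14.8), tolerance = 1e-9)
  # CI by the explicit Fisher-z formula
  z <- atanh(res$r)
  half <- qnorm(0.975) / sqrt(5 - 3)
  expect_equal(res$ci_low, tanh(z - half), tolerance = 1e-9)
  expect_equal(res$ci_high, tanh(z + half), tolerance = 1e-9)
  # p-value from the t transform
  tstat <- res$r * sqrt((5 - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), df = 3), tolerance = 1e-9)
  expect_error(pearson_ci(rep(1, 5), 1:5), class = "fs_undefined_correlation")
})

test_that("covariate correlation table flags constants instead of crashing", {
  set.seed(15)
  covs <- data.frame(a = rnorm(30), b = rnorm(30), const = rep(2, 30))
  tab <- correlate_with_covariates(rnorm(30), covs)
  expect_identical(nrow(tab), 3L)
  expect_false(tab$defined[tab$variable == "const"])
  expect_true(all(tab$defined[tab$variable %in% c("a", "b")]))
  ok <- tab[tab$defined, ]
  expect_true(all(ok$ci_low <= ok$r & ok$r <= ok$ci_high))
})

test_that("covariate-linked cohorts yield intervals covering the built-in correlation", {
  # with the link on, updrs_total is drawn with r = -0.6 to the smile gain
  hits <- 0L
  n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(n_patient = 70, n_control = 1, rng_seed = 200 + s,
                         covariate_link = TRUE)
    coh <- generate_cohort(cfg, render = "none")
    pat <- which(coh$manifest$group == "patient")
    gains <- vapply(coh$subjects[pat], function(x) x$params$smile_angle_gain,
                    numeric(1))
    res <- pearson_ci(gains, coh$manifest$updrs_total[pat])
    if (res$ci_low <= -0.6 && -0.6 <= res$ci_high) hits <- hits + 1L
  }
  # nominal 95% coverage: at most 3 misses in 20 is within binomial bounds
  expect_gte(hits, n_rep - 3L)
})

test_that("repeated-measures sample size follows the noncentral-F search", {
  # m = 1 reduces to a classic two-group ANOVA (f = 0.4 ~ d = 0.8)
  expect_identical(rm_anova_sample_size(0.4, 0.05, 0.95, 2, 1, 0.5), 84L)
  # independent check: power at the returned N brackets the target
  n <- rm_anova_sample_size(0.25, 0.05, 0.80, 3, 4, 0.3)
  expect_gte(rm_anova_power(n, 0.25, 0.05, 3, 4, 0.3), 0.80)
  expect_lt(rm_anova_power(n - 3, 0.25, 0.05, 3, 4, 0.3), 0.80)
  expect_identical(n %% 3L, 0L)
  # rho -> 1 collapses the repetition benefit to m = 1
  expect_identical(rm_anova_sample_size(0.4, 0.05, 0.95, 2, 120, 1),
                   rm_anova_sample_size(0.4, 0.05, 0.95, 2, 1, 0.7))
  expect_error(rm_anova_sample_size(0), class = "fs_config_error")
})

test_that("sample size is monotone in effect, repetitions, power and rho", {
  base <- rm_anova_sample_size(0.3, 0.05, 0.9, 2, 10, 0.5)
  expect_lte(rm_anova_sample_size(0.4, 0.05, 0.9, 2, 10, 0.5), base)
  expect_lte(rm_anova_sample_size(0.3, 0.05, 0.9, 2, 20, 0.5), base)
  expect_gte(rm_anova_sample_size(0.3, 0.05, 0.95, 2, 10, 0.5), base)
  expect_gte(rm_anova_sample_size(0.3, 0.05, 0.9, 2, 10, 0.8), base)
})
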