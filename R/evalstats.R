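# ROC/AUC/Youden evaluation, confusion-matrix metrics, clinical-covariate
# correlations with Fisher-z intervals, and the repeated-measures ANOVA
# sample-size calculation.

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold (prediction = positive when
#' `score >= threshold`), plus +/-Inf endpoints. The AUC is the trapezoidal
#' integral of the (FPR, TPR) curve, which equals the pairwise concordance
#' probability with tied score pairs counted 0.5.
#'
#' @param scores numeric class-1 propensity scores.
#' @param labels 0/1 (or logical) labels, 1 = positive (patient).
#' @return An object of class `fs_roc`: a list with `points` (data.frame of
#'   threshold, tpr, fpr ordered by decreasing threshold), `auc`,
#'   `youden_j`, `youden_threshold`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) {
    fs_error("fs_config_error", "scores and labels differ in length")
  }
  if (!all(labels %in% c(0L, 1L)) || length(unique(labels)) < 2L) {
    fs_error("fs_config_error", "need both classes among the labels")
  }
  np <- sum(labels == 1L)
  nn <- sum(labels == 0L)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores >= t & labels == 1L) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & labels == 0L) / nn, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  res <- structure(
    list(points = data.frame(threshold = thr, tpr = tpr, fpr = fpr),
         auc = auc, scores = scores, labels = labels),
    class = "fs_roc"
  )
  yt <- youden_threshold(res)
  res$youden_j <- yt$j
  res$youden_threshold <- yt$threshold
  res
}

#' @export
print.fs_roc <- function(x, ...) {
  cat(sprintf("<ROC> AUC %.4f, Youden J %.4f at threshold %.4g (%d points)\n",
              x$auc, x$youden_j, x$youden_threshold, nrow(x$points)))
  invisible(x)
}

#' Youden-optimal threshold of a ROC curve
#'
#' Maximizes J = TPR - FPR over the threshold sweep; among maximizers the
#' one with the highest TPR is chosen. The reported threshold is the
#' midpoint between the two adjacent distinct scores straddling the cut
#' (when the cut includes every score, `min(scores) - 1`; when it excludes
#' all, `max(scores) + 1`).
#'
#' @param roc an `fs_roc` from [roc_auc()].
#' @return A list with `threshold` and `j`.
#' @export
youden_threshold <- function(roc) {
  pts <- roc$points
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  # tpr is nondecreasing along the sweep: the last tie has the highest TPR
  k <- best[length(best)]
  cut <- pts$threshold[k]
  sc <- sort(unique(roc$scores))
  included <- sc[sc >= cut]
  excluded <- sc[sc < cut]
  threshold <- if (length(included) == 0L) {
    max(sc) + 1
  } else if (length(excluded) == 0L) {
    min(sc) - 1
  } else {
    (min(included) + max(excluded)) / 2
  }
  list(threshold = threshold, j = max(j))
}

#' Confusion-matrix classification metrics
#'
#' @param labels true 0/1 labels.
#' @param predictions hard 0/1 predictions.
#' @return A list with counts `tp`, `fp`, `fn`, `tn` and rates `accuracy`,
#'   `precision`, `recall`, `f_measure`; `precision_defined` is `FALSE`
#'   (and precision/F are `NA`) when no positive predictions exist.
#' @export
classification_metrics <- function(labels, predictions) {
  labels <- as.integer(labels)
  predictions <- as.integer(predictions)
  if (length(labels) != length(predictions)) {
    fs_error("fs_config_error", "labels and predictions differ in length")
  }
  tp <- sum(labels == 1L & predictions == 1L)
  fp <- sum(labels == 0L & predictions == 1L)
  fn <- sum(labels == 1L & predictions == 0L)
  tn <- sum(labels == 0L & predictions == 0L)
  precision_defined <- (tp + fp) > 0L
  precision <- if (precision_defined) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f <- if (precision_defined && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / length(labels),
       precision = precision, recall = recall, f_measure = f,
       precision_defined = precision_defined)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment r; two-sided p from `t = r * sqrt((n-2)/(1-r^2))`; CI
#' `tanh(atanh(r) +/- z / sqrt(n-3))` (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors (pairwise complete values are used).
#' @param conf confidence level (default 0.95).
#' @return A list with `r`, `p_value`, `ci_low`, `ci_high`, `n`.
#' @export
pearson_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    fs_error("fs_config_error", "need at least 3 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    fs_error("fs_undefined_correlation", "zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = conf)
  ci <- if (!is.null(ct$conf.int)) as.numeric(ct$conf.int) else c(NA_real_, NA_real_)
  list(r = unname(ct$estimate), p_value = ct$p.value,
       ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Correlate a model output with clinical covariates
#'
#' One Pearson correlation per covariate column, reported in the layout of
#' a clinical correlation table (variable, n, p, r, 95% CI). Intended for
#' the patient group only; raw p-values are reported without multiplicity
#' correction. Constant or insufficient covariates yield an `NA` row with
#' `defined = FALSE` rather than an error.
#'
#' @param values numeric vector (model scores or a facial feature), one per
#'   row of `covariates`.
#' @param covariates data.frame of numeric covariate columns.
#' @param conf confidence level.
#' @return A data.frame with columns `variable`, `n`, `p_value`, `r`,
#'   `ci_low`, `ci_high`, `defined`.
#' @export
correlate_with_covariates <- function(values, covariates, conf = 0.95) {
  stopifnot(nrow(covariates) == length(values))
  rows <- lapply(names(covariates), function(nm) {
    res <- tryCatch(
      pearson_ci(values, as.numeric(covariates[[nm]]), conf = conf),
      fs_error = function(e) NULL
    )
    if (is.null(res)) {
      data.frame(variable = nm, n = sum(is.finite(as.numeric(covariates[[nm]]))),
                 p_value = NA_real_, r = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, defined = FALSE)
    } else {
      data.frame(variable = nm, n = res$n, p_value = res$p_value, r = res$r,
                 ci_low = res$ci_low, ci_high = res$ci_high, defined = TRUE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Power of a between-groups repeated-measures ANOVA design
#'
#' Noncentral-F power for the between-subjects factor with k groups, m
#' repeated measurements correlated rho, total N subjects and Cohen effect
#' size f: noncentrality `lambda = f^2 * N * m / (1 + (m - 1) * rho)`,
#' `df1 = k - 1`, `df2 = N - k` (the G*Power convention for
#' "ANOVA: repeated measures, between factors").
#'
#' @param n_total total number of subjects across groups.
#' @param f_effect Cohen's f.
#' @param alpha type-I error rate.
#' @param k_groups number of groups.
#' @param m_measurements repeated measurements per subject.
#' @param rho correlation among repeated measurements, in \[0, 1\].
#' @return Power (probability of rejecting at level alpha).
#' @export
rm_anova_power <- function(n_total, f_effect, alpha = 0.05, k_groups = 2,
                           m_measurements = 1, rho = 0.5) {
  mult <- m_measurements / (1 + (m_measurements - 1) * rho)
  lambda <- f_effect^2 * n_total * mult
  df1 <- k_groups - 1
  df2 <- n_total - k_groups
  if (df2 < 1) return(0)
  fcrit <- stats::qf(1 - alpha, df1, df2)
  1 - stats::pf(fcrit, df1, df2, ncp = lambda)
}

#' Minimum sample size for a between-groups repeated-measures ANOVA
#'
#' Smallest balanced total N (a multiple of `k_groups`) whose
#' [rm_anova_power()] reaches the target.
#'
#' @param f_effect Cohen's f (> 0).
#' @param alpha type-I error rate in (0, 1).
#' @param power target power in (alpha, 1).
#' @param k_groups number of groups.
#' @param m_measurements repeated measurements per subject.
#' @param rho correlation among repeated measurements in \[0, 1\].
#' @param n_max search cap.
#' @return Total N (integer).
#' @export
rm_anova_sample_size <- function(f_effect, alpha = 0.05, power = 0.95,
                                 k_groups = 2, m_measurements = 1, rho = 0.5,
                                 n_max = 1e6) {
  if (!is_scalar(f_effect) || f_effect <= 0) {
    fs_error("fs_config_error", "effect size f must be > 0 for a finite N")
  }
  if (alpha <= 0 || alpha >= 1 || power <= alpha || power >= 1) {
    fs_error("fs_config_error", "need 0 < alpha < power < 1")
  }
  if (rho < 0 || rho > 1) {
    fs_error("fs_config_error", "rho must lie in [0, 1]")
  }
  n <- k_groups * 2 # smallest balanced design with df2 >= 1
  while (n <= n_max) {
    if (rm_anova_power(n, f_effect, alpha, k_groups, m_measurements, rho) >= power) {
      return(as.integer(n))
    }
    n <- n + k_groups
  }
  fs_error("fs_config_error", "target power unreachable within search cap")
}
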