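# Dataset splitting, leakage-safe standardization/fusion, and the three
# classical classifier families (SVM, KNN, random forest) behind a common
# train/score surface.

#' Stratified train/test split
#'
#' Splits subjects so that class proportions in train and test match the
#' overall proportion within one subject (largest-remainder allocation of
#' the per-class training counts). Deterministic given the seed; splitting
#' is per subject (one feature row each), never per frame.
#'
#' @param labels 0/1 labels, one per subject row.
#' @param n_train,n_test split sizes; must sum to `length(labels)`.
#' @param seed integer seed.
#' @return A list of class `dataset_split`: integer `train_idx`,
#'   `test_idx`, and `seed`.
#' @export
split_dataset <- function(labels, n_train, n_test, seed) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n_train + n_test != n) {
    fs_error("fs_config_error", sprintf(
      "n_train + n_test = %d does not match %d rows", n_train + n_test, n
    ))
  }
  if (n_train < 1 || n_test < 1) {
    fs_error("fs_config_error", "both split sides must be nonempty")
  }
  classes <- sort(unique(labels))
  frac <- n_train / n
  base <- vapply(classes, function(cl) floor(frac * sum(labels == cl)), numeric(1))
  rem <- vapply(classes, function(cl) frac * sum(labels == cl), numeric(1)) - base
  extra <- n_train - sum(base)
  take <- base
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    take[ord[seq_len(extra)]] <- take[ord[seq_len(extra)]] + 1
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      idx <- which(labels == classes[i])
      sample(idx, take[i])
    }))
  })
  train_idx <- sort(train_idx)
  structure(
    list(train_idx = train_idx,
         test_idx = setdiff(seq_len(n), train_idx),
         seed = as.integer(seed)),
    class = "dataset_split"
  )
}

#' Fit per-feature standardization statistics
#'
#' Means and SDs estimated on the training rows only, so test rows never
#' influence the scaling (no leakage).
#'
#' @param x numeric matrix of training rows.
#' @return A list of class `standardization_stats` with `mean`, `sd`, and
#'   logical `zero_sd` flags.
#' @export
fit_standardization <- function(x) {
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  structure(list(mean = m, sd = s, zero_sd = s == 0),
            class = "standardization_stats")
}

#' Apply standardization statistics
#'
#' Z-scores each column with the fitted training mean/SD; columns whose
#' training SD was zero are set to 0.
#'
#' @param x numeric matrix.
#' @param stats a `standardization_stats`.
#' @return The standardized matrix.
#' @export
apply_standardization <- function(x, stats) {
  if (ncol(x) != length(stats$mean)) {
    fs_error("fs_layout_error", "column count does not match the fitted stats")
  }
  z <- sweep(x, 2, stats$mean, "-")
  sd_safe <- ifelse(stats$zero_sd, 1, stats$sd)
  z <- sweep(z, 2, sd_safe, "/")
  z[, stats$zero_sd] <- 0
  z
}

#' Standardize and fuse geometric and texture features
#'
#' Column-binds the geometric and texture blocks (subject order must match),
#' fits standardization on the training rows, and returns the z-scored
#' combined matrix.
#'
#' @param geom numeric matrix of geometric features (rows = subjects).
#' @param tex numeric matrix of texture features, same row order.
#' @param train_idx training row indices on which to fit the scaling.
#' @param stats optional pre-fitted `standardization_stats` (overrides
#'   `train_idx`).
#' @return A list with `matrix` (standardized `[geom | tex]`) and `stats`.
#' @export
standardize_and_combine <- function(geom, tex, train_idx = NULL, stats = NULL) {
  if (nrow(geom) != nrow(tex)) {
    fs_error("fs_config_error", "geometric and texture blocks differ in rows")
  }
  if (!is.null(rownames(geom)) && !is.null(rownames(tex)) &&
      !identical(rownames(geom), rownames(tex))) {
    fs_error("fs_config_error", "subject ordering differs between blocks")
  }
  combined <- cbind(geom, tex)
  if (is.null(stats)) {
    if (is.null(train_idx)) {
      fs_error("fs_config_error", "supply train_idx or pre-fitted stats")
    }
    stats <- fit_standardization(combined[train_idx, , drop = FALSE])
  }
  list(matrix = apply_standardization(combined, stats), stats = stats)
}

#' Train a classifier
#'
#' Defaults: SVM with RBF kernel, cost 1 and bandwidth `gamma =
#' 1 / (p * mean feature variance)` (the "scale" rule); KNN with k = 5 and
#' Euclidean distance; random forest with 100 trees and `floor(sqrt(p))`
#' candidate features per split. The SVM decision sign is oriented on the
#' training data so that larger scores mean class 1.
#'
#' @param x numeric feature matrix (training rows).
#' @param y 0/1 labels.
#' @param algo `"svm"`, `"knn"` or `"rf"`.
#' @param hyper optional overrides: `cost`, `gamma` (svm); `k` (knn);
#'   `ntree`, `mtry` (rf).
#' @param seed integer training seed (used by the random forest).
#' @return An object of class `fs_model`.
#' @export
train_classifier <- function(x, y, algo = c("svm", "knn", "rf"),
                             hyper = list(), seed = 1) {
  algo <- match.arg(algo)
  x <- as.matrix(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    fs_error("fs_config_error", "need at least 2 training rows per class")
  }
  p <- ncol(x)
  fit <- switch(algo,
    svm = {
      gamma <- hyper$gamma %||% {
        v <- mean(apply(x, 2, stats::var))
        if (v > 0) 1 / (p * v) else 1 / p
      }
      mod <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                        kernel = "radial", cost = hyper$cost %||% 1,
                        gamma = gamma, scale = FALSE)
      dv <- as.numeric(attr(stats::predict(mod, x, decision.values = TRUE),
                            "decision.values"))
      orient <- if (mean(dv[y == 1]) >= mean(dv[y == 0])) 1 else -1
      list(model = mod, orientation = orient)
    },
    knn = list(train = x, cl = factor(y, levels = c(0, 1)),
               k = hyper$k %||% 5L),
    rf = with_seed(seed, {
      randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        ntree = hyper$ntree %||% 100L,
        mtry = hyper$mtry %||% max(1L, floor(sqrt(p)))
      )
    })
  )
  structure(
    list(algorithm = algo, fit = fit, layout = colnames(x),
         n_features = p, seed = as.integer(seed), hyper = hyper),
    class = "fs_model"
  )
}

#' Score subjects with a trained classifier
#'
#' Returns a monotone class-1 propensity in \[0, 1\]: the tree-vote
#' fraction for the random forest, the neighbor-vote fraction for KNN, and
#' the oriented SVM decision value mapped through the logistic function.
#'
#' @param model an `fs_model`.
#' @param x feature matrix with the same column layout as at training.
#' @return Numeric scores in \[0, 1\].
#' @export
score_classifier <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features ||
      (!is.null(model$layout) && !is.null(colnames(x)) &&
       !identical(colnames(x), model$layout))) {
    fs_error("fs_layout_error", "feature layout does not match the trained model")
  }
  switch(model$algorithm,
    svm = {
      dv <- as.numeric(attr(
        stats::predict(model$fit$model, x, decision.values = TRUE),
        "decision.values"
      ))
      stats::plogis(model$fit$orientation * dv)
    },
    knn = {
      pred <- class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k,
                         prob = TRUE, use.all = TRUE)
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    rf = unname(stats::predict(model$fit, x, type = "prob")[, "1"])
  )
}

#' @export
print.fs_model <- function(x, ...) {
  cat(sprintf("<fs_model> %s on %d features (seed %d)\n",
              x$algorithm, x$n_features, x$seed))
  invisible(x)
}

#' Evaluate a trained model on a labeled feature matrix
#'
#' Scores the rows, builds the ROC, and computes confusion-matrix metrics
#' with hard labels taken at the Youden-optimal threshold of that ROC.
#'
#' @param model an `fs_model`.
#' @param x feature matrix.
#' @param y 0/1 labels.
#' @return A list with `scores`, `roc` (class `fs_roc`) and `metrics`.
#' @export
evaluate_model <- function(model, x, y) {
  sc <- score_classifier(model, x)
  roc <- roc_auc(sc, y)
  preds <- as.integer(sc >= roc$youden_threshold)
  list(scores = sc, roc = roc,
       metrics = classification_metrics(y, preds))
}
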