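# Subject-specific medication-state decoder: linear soft-margin SVM on
# standardized band-power features, class balancing, unshuffled stratified
# contiguous 10-fold cross-validation, per-fold weight profiles and a
# fold-averaged ROC. Class coding: ON = +1, OFF = -1, so a positive band
# weight means standardized power in that band is higher on medication.

#' Balance OFF and ON sample counts
#'
#' Both classes are reduced to `min(n_off, n_on)` samples. By default the
#' surplus is removed deterministically from the chronological end of the
#' larger class; `mode = "random"` subsamples with a seed instead.
#'
#' @param table an `sdr_feature_table`.
#' @param mode `"tail"` (default) or `"random"`.
#' @param seed seed for `mode = "random"`.
#' @return balanced feature table.
#' @export
balance_classes <- function(table, mode = c("tail", "random"), seed = 0) {
  mode <- match.arg(mode)
  n <- vapply(SDR_CONDITIONS, function(cond) sum(table$condition == cond),
              numeric(1))
  if (any(n == 0)) stopf("condition %s has no samples",
                         paste(SDR_CONDITIONS[n == 0], collapse = ", "))
  m <- min(n)
  keep <- unlist(lapply(SDR_CONDITIONS, function(cond) {
    idx <- which(table$condition == cond)
    if (length(idx) <= m) return(idx)
    if (mode == "tail") idx[seq_len(m)]
    else with_seed(seed, sort(sample(idx, m)))
  }))
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standardize feature columns to zero mean, unit variance
#'
#' `scope = "global"` fits on all samples (the default used for final
#' decoding); `scope = "per_fold"` is handled inside [cross_validate()] by
#' fitting on training folds only.
#'
#' @param table feature table.
#' @param center,scale optional pre-fitted parameters (named numeric).
#' @return list with `table` (standardized) and `params` (center, scale).
#' @export
standardize_features <- function(table, center = NULL, scale = NULL) {
  cols <- feature_columns(table)
  if (!length(cols)) stopf("no feature columns (bp_*) found")
  if (is.null(center)) center <- vapply(table[cols], mean, numeric(1))
  if (is.null(scale)) scale <- vapply(table[cols], stats::sd, numeric(1))
  zero <- cols[scale == 0 | !is.finite(scale)]
  if (length(zero)) stopf("zero-variance feature(s): %s", paste(zero, collapse = ", "))
  for (j in seq_along(cols))
    table[[cols[j]]] <- (table[[cols[j]]] - center[j]) / scale[j]
  list(table = table, params = list(center = center, scale = scale))
}

#' Assign unshuffled, stratified, contiguous cross-validation folds
#'
#' Within each class, samples in chronological order are cut into `k`
#' contiguous blocks; the first `n %% k` blocks get `ceiling(n/k)` samples.
#' Fold i is the union of block i from each class, so test folds always
#' contain both classes and no shuffling occurs.
#'
#' @param n_samples_per_class samples per class (>= k).
#' @param k number of folds (default 10).
#' @return integer fold label (1..k) per within-class chronological index;
#'   apply per class.
#' @export
assign_folds <- function(n_samples_per_class, k = 10) {
  n <- n_samples_per_class
  if (n < k) stopf("need at least k = %d samples per class, got %d", k, n)
  sizes <- rep(floor(n / k), k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Train a linear soft-margin SVM
#'
#' Minimises `0.5 * ||w||^2 + C * sum(hinge)` through sequential minimal
#' optimisation on the dual (compiled; maximal-violating-pair selection).
#'
#' @param X numeric matrix (samples x features).
#' @param y labels in `{-1, +1}`.
#' @param C box constraint (> 0).
#' @param tol KKT-gap stopping tolerance.
#' @param max_iter iteration cap.
#' @return object of class `sdr_svm`: list with `weights`, `bias`,
#'   `objective`, `box_constraint`, `converged`.
#' @export
train_linear_svm <- function(X, y, C, tol = 1e-6, max_iter = 2000000L) {
  X <- as.matrix(X)
  if (!all(y %in% c(-1, 1))) stopf("labels must be coded -1/+1")
  if (length(unique(y)) < 2) stopf("training data contain a single class")
  if (!all(is.finite(X))) stopf("non-finite feature values")
  assert_scalar_num(C, "C", positive = TRUE)
  fit <- .svm_smo_cpp(X, as.numeric(y), C, tol = tol, max_iter = as.integer(max_iter))
  structure(list(weights = as.numeric(fit$weights), bias = fit$bias,
                 alpha = as.numeric(fit$alpha), objective = fit$objective,
                 box_constraint = C, converged = fit$converged,
                 iterations = fit$iterations),
            class = "sdr_svm")
}

#' Decision values of a linear SVM
#' @param object an `sdr_svm`.
#' @param newdata numeric matrix of (already standardized) features.
#' @param ... unused.
#' @return numeric decision values; `sign()` gives the predicted class.
#' @export
predict.sdr_svm <- function(object, newdata, ...) {
  as.numeric(as.matrix(newdata) %*% object$weights + object$bias)
}

svm_objective <- function(X, y, w, b, C) {
  margins <- 1 - y * (as.matrix(X) %*% w + b)
  0.5 * sum(w^2) + C * sum(pmax(0, margins))
}

#' Cross-validated medication-state decoding for one subject
#'
#' Balances classes, standardizes features, assigns unshuffled stratified
#' contiguous folds, then trains one linear SVM per fold on the remaining
#' k-1 folds and tests on the held-out fold. Stores per-fold accuracies,
#' weight vectors and test decision values; summarises with the median fold
#' accuracy and the fold-averaged ROC.
#'
#' @param table `sdr_feature_table` for one subject (both conditions).
#' @param C box constraint.
#' @param k folds (default 10).
#' @param standardize_scope `"global"` (default) or `"per_fold"`.
#' @param balance_mode passed to [balance_classes()].
#' @param svm_tol,svm_max_iter solver controls. The iteration cap bounds the
#'   cost of hopeless fits (very large C on non-separable data, where the
#'   dual creeps); fits that matter converge far below it.
#' @return object of class `sdr_decode_result`.
#' @export
cross_validate <- function(table, C, k = 10,
                           standardize_scope = c("global", "per_fold"),
                           balance_mode = "tail",
                           svm_tol = 1e-4, svm_max_iter = 30000L) {
  standardize_scope <- match.arg(standardize_scope)
  table <- balance_classes(table, mode = balance_mode)
  cols <- feature_columns(table)
  n_per_class <- sum(table$condition == "OFF")
  folds_within <- assign_folds(n_per_class, k)
  fold <- integer(nrow(table))
  for (cond in SDR_CONDITIONS) fold[table$condition == cond] <- folds_within
  y <- ifelse(table$condition == "ON", 1, -1)

  if (standardize_scope == "global")
    table <- standardize_features(table)$table
  X_all <- as.matrix(table[cols])

  fold_acc <- numeric(k)
  fold_w <- matrix(NA_real_, k, length(cols), dimnames = list(NULL, cols))
  fold_b <- numeric(k)
  decisions <- vector("list", k)
  test_labels <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- fold != i; te <- !tr
    X_tr <- X_all[tr, , drop = FALSE]; X_te <- X_all[te, , drop = FALSE]
    if (standardize_scope == "per_fold") {
      mu <- colMeans(X_tr); sdev <- apply(X_tr, 2, stats::sd)
      if (any(sdev == 0)) stopf("zero-variance feature in training fold %d", i)
      X_tr <- sweep(sweep(X_tr, 2, mu), 2, sdev, "/")
      X_te <- sweep(sweep(X_te, 2, mu), 2, sdev, "/")
    }
    fit <- train_linear_svm(X_tr, y[tr], C, tol = svm_tol, max_iter = svm_max_iter)
    dv <- predict(fit, X_te)
    pred <- ifelse(dv >= 0, 1, -1)
    fold_acc[i] <- mean(pred == y[te])
    fold_w[i, ] <- fit$weights
    fold_b[i] <- fit$bias
    decisions[[i]] <- dv
    test_labels[[i]] <- y[te]
  }
  roc <- averaged_roc(decisions, test_labels)
  structure(list(subject_id = table$subject_id[1],
                 fold_accuracies = fold_acc,
                 fold_weight_vectors = fold_w, fold_biases = fold_b,
                 median_accuracy = stats::median(fold_acc),
                 roc = roc, box_constraint = C,
                 n_samples_per_class = n_per_class, k = k,
                 decision_values = decisions, test_labels = test_labels),
            class = "sdr_decode_result")
}

#' @export
print.sdr_decode_result <- function(x, ...) {
  cat(sprintf("<sdr_decode_result> subject %s: median accuracy %.3f (C = %.3g, %d/class)\n",
              x$subject_id, x$median_accuracy, x$box_constraint,
              x$n_samples_per_class))
  invisible(x)
}

roc_points <- function(dv, labels) {
  # threshold sweep; returns step-function points sorted by FPR
  ord <- order(dv, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab == 1); fp <- cumsum(lab == -1)
  tpr <- c(0, tp / sum(lab == 1))
  fpr <- c(0, fp / sum(lab == -1))
  list(fpr = fpr, tpr = tpr)
}

#' Fold-averaged ROC curve
#'
#' Per-fold ROC curves from the stored test decision values, vertically
#' averaged on a fixed false-positive-rate grid (0 to 1 in steps of 0.01);
#' area under the averaged curve by the trapezoid rule. Folds whose test
#' set lacks one class are skipped with a warning.
#'
#' @param decisions list of per-fold decision-value vectors.
#' @param labels list of per-fold label vectors (-1/+1).
#' @param fpr_grid grid for vertical averaging.
#' @return list with `fpr`, `tpr` (averaged), `area`, `per_fold_area`.
#' @export
averaged_roc <- function(decisions, labels, fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(decisions) == length(labels))
  curves <- list(); areas <- numeric(0)
  for (i in seq_along(decisions)) {
    lab <- labels[[i]]
    if (length(unique(lab)) < 2) {
      warnf("fold %d has a single-class test set; skipped in ROC averaging", i)
      next
    }
    pts <- roc_points(decisions[[i]], lab)
    # step interpolation: best TPR achieved at FPR <= grid value
    tpr_g <- vapply(fpr_grid, function(g) max(pts$tpr[pts$fpr <= g + 1e-12]),
                    numeric(1))
    curves[[length(curves) + 1L]] <- tpr_g
    areas <- c(areas, sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2))
  }
  if (!length(curves)) stopf("all folds degenerate: no ROC can be computed")
  tpr_avg <- Reduce(`+`, curves) / length(curves)
  area <- sum(diff(fpr_grid) * (head(tpr_avg, -1) + tpr_avg[-1]) / 2)
  list(fpr = fpr_grid, tpr = tpr_avg, area = area, per_fold_area = areas)
}

#' Frequency-band weight profile of a decode result
#'
#' Mean and standard deviation of each band's SVM weight across folds.
#' Positive mean weight: standardized power in that band is higher under
#' medication (ON coded +1).
#'
#' @param result an `sdr_decode_result`.
#' @return data frame with `band`, `mean_weight`, `sd_weight`.
#' @export
weight_profile <- function(result) {
  stopifnot(inherits(result, "sdr_decode_result"))
  W <- result$fold_weight_vectors
  data.frame(band = colnames(W),
             mean_weight = colMeans(W),
             sd_weight = apply(W, 2, stats::sd),
             row.names = NULL)
}
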