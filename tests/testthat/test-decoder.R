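test_that("class balancing trims the chronological tail of the larger class", {
  tab <- make_gaussian_table(71, seed = 1)
  expect_equal(nrow(balance_classes(tab)), 142)   # already balanced
  tab_cut <- tab[!(tab$condition == "ON" & tab$snippet_index > 60), ]
  bal <- balance_classes(tab_cut)
  expect_equal(sum(bal$condition == "OFF"), 60)
  expect_equal(sum(bal$condition == "ON"), 60)
  expect_equal(max(bal$snippet_index[bal$condition == "OFF"]), 60)
  empty <- tab[tab$condition == "OFF", ]
  expect_error(balance_classes(empty), "no samples")
  # seeded random mode is reproducible
  r1 <- balance_classes(tab_cut, mode = "random", seed = 4)
  r2 <- balance_classes(tab_cut, mode = "random", seed = 4)
  expect_equal(r1, r2)
})

test_that("standardization hits zero mean unit variance and reports params", {
  tab <- make_gaussian_table(30, seed = 2)
  tab$bp_1 <- tab$bp_1 * 2 + 5
  out <- standardize_features(tab)
  m <- as.matrix(out$table[grep("^bp_", names(out$table))])
  expect_lt(max(abs(colMeans(m))), 1e-10)
  expect_equal(apply(m, 2, stats::sd), rep(1, 4), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_equal(out$params$center[["bp_1"]], mean(5 + 2 * make_gaussian_table(30, seed = 2)$bp_1))
  again <- standardize_features(out$table)
  expect_equal(as.data.frame(again$table), as.data.frame(out$table),
               tolerance = 1e-10)
  tab$bp_2 <- 1
  expect_error(standardize_features(tab), "bp_2")
})

test_that("fold assignment is contiguous, stratified and exhaustive", {
  expect_equal(assign_folds(10, 10), 1:10)
  f23 <- assign_folds(23, 10)
  expect_equal(as.integer(table(f23)), c(3, 3, 3, 2, 2, 2, 2, 2, 2, 2))
  expect_true(all(diff(f23) >= 0))        # contiguous blocks
  expect_length(f23, 23)
  expect_error(assign_folds(9, 10), "at least")
})

test_that("the SVM solves the separable 1-D case in closed form", {
  X <- matrix(c(-1, 1), 2, 1)
  f <- train_linear_svm(X, c(-1, 1), C = 1e6)
  expect_equal(f$weights, 1, tolerance = 1e-6)
  expect_equal(f$bias, 0, tolerance = 1e-6)
  expect_equal(predict(f, matrix(c(-2, 0.5))), c(-2, 0.5), tolerance = 1e-5)
  expect_error(train_linear_svm(X, c(1, 1), 1), "single class")
  expect_error(train_linear_svm(matrix(c(NA, 1), 2, 1), c(-1, 1), 1), "finite")
})

test_that("swapping class labels negates weights and bias", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(-1, 1), 10)
  a <- train_linear_svm(X, y, C = 3, tol = 1e-8)
  b <- train_linear_svm(X, -y, C = 3, tol = 1e-8)
  expect_equal(a$weights, -b$weights, tolerance = 1e-5)
  expect_equal(a$bias, -b$bias, tolerance = 1e-5)
})

test_that("rescaling features then re-standardizing leaves predictions fixed", {
  tab <- make_gaussian_table(30, shift = c(1, 0, 0, 0), seed = 9)
  res1 <- cross_validate(tab, C = 1)
  tab2 <- tab
  for (cl in grep("^bp_", names(tab2))) tab2[[cl]] <- tab2[[cl]] * 2
  res2 <- cross_validate(tab2, C = 1)
  expect_equal(res1$fold_accuracies, res2$fold_accuracies, tolerance = 1e-8)
  expect_equal(res1$fold_weight_vectors, res2$fold_weight_vectors,
               tolerance = 1e-4)
})

test_that("cross-validation is chance-level on pure noise, perfect on separation", {
  accs <- vapply(1:10, function(s) {
    cross_validate(make_gaussian_table(40, seed = 100 + s), C = 1)$median_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
  sep <- cross_validate(make_gaussian_table(40, shift = c(10, 0, 0, 0), seed = 3),
                        C = 10)
  expect_equal(sep$fold_accuracies, rep(1, 10))
  expect_length(sep$fold_accuracies, 10)
  expect_true(all(sep$fold_accuracies >= 0 & sep$fold_accuracies <= 1))
  expect_equal(sep$median_accuracy, stats::median(sep$fold_accuracies))
})

test_that("per-fold standardization fits on training folds only", {
  tab <- make_gaussian_table(30, shift = c(2, 0, 0, 0), seed = 12)
  res <- cross_validate(tab, C = 1, standardize_scope = "per_fold")
  expect_length(res$fold_accuracies, 10)
  expect_gt(res$median_accuracy, 0.8)
})

test_that("averaged ROC reproduces hand-computed step curves", {
  # perfect fold
  roc1 <- averaged_roc(list(c(2, 1, -1, -2)), list(c(1, 1, -1, -1)))
  expect_equal(roc1$area, 1)
  expect_equal(roc1$tpr[1], 1)  # at fpr 0 the step already reaches tpr 1
  # fold with one inversion: dv (2,-1,1,-2), labels (1,1,-1,-1)
  # sweep: tpr steps 0.5 at fpr 0; fpr 0.5 at tpr 0.5; tpr 1; fpr 1
  roc2 <- averaged_roc(list(c(2, -1, 1, -2)), list(c(1, 1, -1, -1)))
  expect_equal(roc2$tpr[roc2$fpr == 0], 0.5)
  expect_equal(roc2$tpr[roc2$fpr == 0.5], 1.0)
  expect_equal(roc2$area, 0.75, tolerance = 0.01)
  # vertical average of the two folds
  both <- averaged_roc(list(c(2, 1, -1, -2), c(2, -1, 1, -2)),
                       list(c(1, 1, -1, -1), c(1, 1, -1, -1)))
  expect_equal(both$tpr[both$fpr == 0], 0.75)
  expect_equal(both$tpr[both$fpr == 0.5], 1.0)
  # labels-as-decisions is perfect; label-independent decisions are ~ 0.5
  expect_equal(averaged_roc(list(c(1, 1, -1, -1) * 5), list(c(1, 1, -1, -1)))$area, 1)
  set.seed(31)
  areas <- replicate(50, {
    y <- rep(c(1, -1), each = 10)
    averaged_roc(list(rnorm(20)), list(y))$area
  })
  expect_equal(mean(areas), 0.5, tolerance = 0.08)
  expect_warning(
    r <- averaged_roc(list(c(1, 2), c(1, -1)), list(c(1, 1), c(1, -1))),
    "single-class")
  expect_error(suppressWarnings(averaged_roc(list(c(1, 2)), list(c(1, 1)))),
               "degenerate")
})

test_that("weight profiles summarise folds with the documented sign convention", {
  res <- cross_validate(make_gaussian_table(40, shift = c(3, 0, 0, 0), seed = 5),
                        C = 10)
  wp <- weight_profile(res)
  expect_equal(nrow(wp), 4)
  expect_equal(nrow(res$fold_weight_vectors), res$k)
  # ON-shifted feature 1 must carry a positive weight
  expect_gt(wp$mean_weight[1], 0)
  expect_equal(which.max(abs(wp$mean_weight)), 1L)
  # identical weights across folds have sd 0
  fake <- res
  fake$fold_weight_vectors <- matrix(1, 10, 4,
                                     dimnames = list(NULL, wp$band))
  expect_equal(weight_profile(fake)$sd_weight, rep(0, 4))
})
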