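test_that("signed-rank exact p matches hand enumeration and classic cases", {
  # six positive differences: one-sided 1/64, two-sided 2/64
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 6), rep(0, 6))
  expect_equal(r$statistic, 21)
  expect_equal(r$p_value, 2 / 64)
  expect_equal(r$n_effective, 6)
  # antisymmetric differences sit at the null centre
  r2 <- wilcoxon_signed_rank(c(-1, 1, -2, 2, -3, 3), rep(0, 6))
  expect_gt(r2$p_value, 0.5)
  expect_error(wilcoxon_signed_rank(c(1, 1), c(1, 1)), "zero")
})

test_that("exact branch equals independent enumeration on random cases", {
  set.seed(19)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    d <- sample(c(-4:-1, 1:4), n, replace = TRUE)  # ties likely
    r <- wilcoxon_signed_rank(d, rep(0, n))
    expect_equal(r$p_value, oracle_signrank_p(d), info = paste("case", i))
  }
  # tie-free cases also agree with R's exact signed-rank distribution
  for (i in 1:10) {
    n <- sample(5:10, 1)
    d <- sample(1:50, n) * sample(c(-1, 1), n, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
    expect_equal(wilcoxon_signed_rank(d, rep(0, n))$p_value, ref)
  }
})

test_that("the large-sample branch approximates the exact p", {
  set.seed(23)
  d <- rnorm(25) + 0.8
  r <- wilcoxon_signed_rank(rep(0, 25), -d)
  # reference: R's normal approximation with continuity correction
  ref <- suppressWarnings(stats::wilcox.test(d, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(r$p_value, ref, tolerance = 1e-6)
  # and it approximates the exact p to the usual large-sample quality
  exact <- suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
  expect_lt(abs(log10(r$p_value) - log10(exact)), 1)
})

test_that("bonferroni caps and preserves order", {
  expect_equal(bonferroni(0.01, m = 7), 0.07)
  expect_equal(bonferroni(0.5, m = 7), 1)
  p <- c(0.04, 0.001, 0.2)
  expect_equal(order(bonferroni(p, m = 7)), order(p))
  expect_true(all(bonferroni(p, m = 7) >= p))
  expect_error(bonferroni(c(0.1, 0.2), m = 1), "family size")
})

test_that("friedman test has df k-1 and matches oracles", {
  set.seed(29)
  X <- matrix(rnorm(20 * 7), 20, 7)
  r <- friedman_test(X)
  expect_equal(r$df, 6)
  ref <- stats::friedman.test(X)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-10)
  # identical columns: statistic 0, p 1
  same <- matrix(rep(rnorm(10), 4), 10, 4)
  r0 <- friedman_test(same)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # tie-corrected statistic matches the first-principles recomputation
  for (i in 1:20) {
    Y <- matrix(sample(0:3, 8 * 4, replace = TRUE), 8, 4)  # heavy ties
    if (sum(apply(Y, 1, stats::sd)) == 0) next
    expect_equal(friedman_test(Y)$statistic, oracle_friedman_stat(Y),
                 tolerance = 1e-10)
  }
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
})

test_that("friedman statistic is invariant to within-subject monotone maps", {
  set.seed(31)
  X <- matrix(rnorm(12 * 5), 12, 5)
  a <- friedman_test(X)$statistic
  Xm <- t(apply(X, 1, function(row) exp(2 * row) + 1))
  expect_equal(friedman_test(Xm)$statistic, a, tolerance = 1e-12)
})

test_that("benjamini-hochberg follows the step-up definition exactly", {
  set.seed(37)
  for (i in 1:100) {
    m <- sample(1:25, 1)
    p <- round(runif(m), 3)
    out <- benjamini_hochberg(p)
    expect_equal(out$rejected, oracle_bh_reject(p), info = paste("case", i))
    expect_equal(out$adjusted, stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
    expect_true(all(out$adjusted >= p - 1e-12))
  }
  z <- benjamini_hochberg(rep(0, 5))
  expect_true(all(z$rejected))
  expect_equal(z$adjusted, rep(0, 5))
  one <- benjamini_hochberg(0.2)
  expect_equal(one$adjusted, 0.2)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("the BH critical p is the largest passing ordered p", {
  p <- c(0.001, 0.008, 0.012, 0.2, 0.9)
  out <- benjamini_hochberg(p, q = 0.05)
  # thresholds i/m*q = .01, .02, .03, .04, .05 -> largest pass is p=0.012
  expect_equal(out$critical_p, 0.012)
  none <- benjamini_hochberg(c(0.5, 0.9), q = 0.05)
  expect_true(is.na(none$critical_p))
  expect_false(any(none$rejected))
})

test_that("spearman matrix equals rank-based pearson with sane extremes", {
  set.seed(41)
  X <- matrix(rnorm(15 * 7), 15, 7)
  X[, 2] <- -X[, 1]
  out <- spearman_matrix(X)
  expect_equal(diag(out$rho), rep(1, 7))
  expect_equal(out$rho[1, 2], -1)
  expect_equal(out$rho, t(out$rho))
  expect_equal(out$rho, stats::cor(X, method = "spearman"), tolerance = 1e-12)
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_error(spearman_matrix(X[1:3, ]), "at least 4")
})

test_that("accuracy regression recovers collinear fits and closed-form R^2", {
  acc <- seq(0.5, 1, length.out = 10)
  ch <- outer(acc, rep(1, 7)) * 2 - 0.3
  out <- suppressWarnings(accuracy_sdr_regression(acc, ch))  # perfect fit
  expect_length(out, 7)
  expect_equal(out$factor_1$r_squared, 1, tolerance = 1e-10)
  expect_equal(out$factor_1$slope, 2, tolerance = 1e-10)
  set.seed(43)
  ch2 <- matrix(rnorm(10 * 7), 10, 7)
  out2 <- accuracy_sdr_regression(acc, ch2)
  for (f in 1:7) {
    expect_equal(out2[[f]]$r_squared, stats::cor(acc, ch2[, f])^2,
                 tolerance = 1e-12)
    expect_gte(out2[[f]]$p_adjusted, out2[[f]]$p_value)
  }
  band <- out2$factor_3$confidence_band
  expect_true(all(band$lower <= band$fit & band$fit <= band$upper))
  expect_error(accuracy_sdr_regression(rep(0.5, 10), ch2), "zero variance")
})

test_that("slope p-values are uniform under the null at the stated level", {
  set.seed(47)
  reject <- replicate(500, {
    acc <- runif(20, 0.4, 1)
    change <- matrix(rnorm(20), 20, 1)
    accuracy_sdr_regression(acc, change)[[1]]$p_value < 0.05
  })
  hits <- sum(reject)
  expect_gte(hits, stats::qbinom(0.005, 500, 0.05))
  expect_lte(hits, stats::qbinom(0.995, 500, 0.05))
})
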