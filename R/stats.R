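# Nonparametric statistics relating clinical change to decoding: paired
# Wilcoxon signed-rank tests with Bonferroni control, a Friedman omnibus
# across the 7 factors, Benjamini-Hochberg post hocs, the Spearman matrix
# of SDR changes, and per-factor regression of clinical change on decoding
# accuracy.

#' Paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped (classic Wilcoxon treatment). For
#' `n_effective <= exact_max` the two-sided p-value is exact, by enumeration
#' of all sign assignments of the |difference| mid-ranks (valid under ties);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param off,on paired numeric vectors.
#' @param exact_max largest `n_effective` for the exact branch (default 12).
#' @return list with `statistic` (sum of positive-difference ranks, V),
#'   `p_value`, `n_effective`, `method`.
#' @export
wilcoxon_signed_rank <- function(off, on, exact_max = 12) {
  if (length(off) != length(on)) stopf("'off' and 'on' must have equal length")
  d <- off - on
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all paired differences are zero: test undefined")
  if (n < 3) stopf("need at least 3 nonzero differences, got %d", n)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  center <- n * (n + 1) / 4
  if (n <= exact_max) {
    # enumerate all 2^n sign assignments of the mid-ranks
    stats_all <- colSums(r * (t(expand.grid(rep(list(c(0, 1)), n)))))
    p <- min(1, 2 * min(mean(stats_all <= V), mean(stats_all >= V)))
    method <- "exact enumeration"
  } else {
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z <- (V - center)
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  list(statistic = V, p_value = p, n_effective = n, method = method)
}

#' Bonferroni adjustment
#'
#' @param p_values raw p-values.
#' @param m family size (defaults to `length(p_values)`; must be >= it).
#' @return adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stopf("family size m = %d < number of p-values", m)
  pmin(1, m * p_values)
}

#' Friedman rank test across repeated measures
#'
#' Chi-square form with mid-ranks and tie correction; df = k - 1 for k
#' conditions. `form = "iman_davenport"` additionally applies the
#' Iman-Davenport F transformation.
#'
#' @param scores numeric matrix, subjects in rows, conditions in columns.
#' @param form `"chisq"` (default) or `"iman_davenport"`.
#' @return list with `statistic`, `p_value`, `df` (and `df2` for the F
#'   form).
#' @export
friedman_test <- function(scores, form = c("chisq", "iman_davenport")) {
  form <- match.arg(form)
  scores <- as.matrix(scores)
  if (any(!is.finite(scores))) stopf("missing or non-finite cells")
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) stopf("need at least 2 subjects and 2 conditions")
  R <- t(apply(scores, 1, rank))
  Rj <- colSums(R)
  S <- sum((Rj - n * (k + 1) / 2)^2)
  denom <- sum(R^2) - n * k * (k + 1)^2 / 4
  if (denom == 0) {
    chi <- 0
  } else {
    chi <- (k - 1) * S / denom
  }
  df <- k - 1
  if (form == "chisq") {
    list(statistic = chi, p_value = stats::pchisq(chi, df, lower.tail = FALSE),
         df = df)
  } else {
    if (chi >= n * (k - 1)) {
      f <- Inf
    } else {
      f <- (n - 1) * chi / (n * (k - 1) - chi)
    }
    df2 <- (n - 1) * (k - 1)
    list(statistic = f,
         p_value = stats::pf(f, df, df2, lower.tail = FALSE),
         df = df, df2 = df2)
  }
}

#' Benjamini-Hochberg step-up procedure
#'
#' @param p_values raw p-values in \[0, 1\].
#' @param q false-discovery rate (default 0.05).
#' @return list with `adjusted` (monotone BH-adjusted p-values, original
#'   order), `critical_p` (largest ordered p passing its step-up threshold;
#'   `NA` if none), `rejected` (logical).
#' @export
benjamini_hochberg <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stopf("p-values must lie in [0, 1]")
  m <- length(p_values)
  ord <- order(p_values)
  ps <- p_values[ord]
  thresh <- (seq_len(m) / m) * q
  pass <- which(ps <= thresh)
  critical_p <- if (length(pass)) ps[max(pass)] else NA_real_
  adj_sorted <- rev(cummin(rev(ps * m / seq_len(m))))
  adj_sorted <- pmin(1, adj_sorted)
  adjusted <- numeric(m)
  adjusted[ord] <- adj_sorted
  rejected <- if (is.na(critical_p)) rep(FALSE, m) else p_values <= critical_p
  list(adjusted = adjusted, critical_p = critical_p, rejected = rejected)
}

#' Spearman correlation matrix of SDR factor changes
#'
#' Pairwise Spearman rho with mid-ranks; p-values from the t approximation.
#'
#' @param changes numeric matrix, subjects in rows, factors in columns.
#' @return list with `rho` and `p` (symmetric matrices, unit diagonal).
#' @export
spearman_matrix <- function(changes) {
  changes <- as.matrix(changes)
  n <- nrow(changes); k <- ncol(changes)
  if (n < 4) stopf("need at least 4 subjects")
  ranks <- apply(changes, 2, rank)
  rho <- stats::cor(ranks)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(rho))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) { p[i, j] <- 0; next }
      r <- rho[i, j]
      if (abs(r) >= 1) { p[i, j] <- 0; next }
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p[i, j] <- 2 * stats::pt(-abs(tstat), n - 2)
    }
  }
  diag(rho) <- 1
  list(rho = rho, p = p)
}

#' Regress clinical factor change on decoding accuracy
#'
#' Per-factor ordinary least squares of the OFF-minus-ON weighted-average
#' factor change on the subject's median cross-validated accuracy. Reports
#' the unadjusted two-sided slope p-value, the Bonferroni-adjusted p across
#' the 7 factors, R-squared, and a 95% pointwise confidence band of the
#' fitted line.
#'
#' @param median_accuracies numeric vector, one per subject.
#' @param factor_changes matrix (subjects x 7) of factor-score changes.
#' @param band_points abscissae for the confidence band (default: 50 points
#'   spanning the accuracy range).
#' @return list of 7 results, each with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `p_adjusted`, `confidence_band` (data frame with
#'   `accuracy`, `fit`, `lower`, `upper`).
#' @export
accuracy_sdr_regression <- function(median_accuracies, factor_changes,
                                    band_points = 50) {
  acc <- as.numeric(median_accuracies)
  ch <- as.matrix(factor_changes)
  if (length(acc) != nrow(ch)) stopf("accuracy and change tables disagree on subjects")
  if (length(acc) < 3) stopf("need at least 3 subjects")
  if (stats::var(acc) == 0) stopf("accuracies have zero variance; slope undefined")
  grid <- seq(min(acc), max(acc), length.out = band_points)
  raw_p <- numeric(ncol(ch))
  out <- vector("list", ncol(ch))
  for (f in seq_len(ncol(ch))) {
    dat <- data.frame(acc = acc, change = ch[, f])
    fit <- stats::lm(change ~ acc, data = dat)
    sm <- summary(fit)
    pv <- sm$coefficients["acc", "Pr(>|t|)"]
    band <- stats::predict(fit, newdata = data.frame(acc = grid),
                           interval = "confidence", level = 0.95)
    raw_p[f] <- pv
    out[[f]] <- list(slope = unname(coef(fit)["acc"]),
                     intercept = unname(coef(fit)["(Intercept)"]),
                     r_squared = sm$r.squared,
                     p_value = pv,
                     confidence_band = data.frame(accuracy = grid,
                                                  fit = band[, "fit"],
                                                  lower = band[, "lwr"],
                                                  upper = band[, "upr"]))
  }
  adj <- bonferroni(raw_p, m = ncol(ch))
  for (f in seq_along(out)) out[[f]]$p_adjusted <- adj[f]
  names(out) <- paste0("factor_", seq_along(out))
  out
}
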