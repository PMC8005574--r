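# One-dimensional Bayesian optimisation of the SVM box constraint C over
# [1e-6, 1e+6], working in u = log10(C) for stationarity across the 12
# decades. Gaussian-process surrogate (constant mean, squared-exponential
# kernel, maximum-likelihood hyperparameters) with expected improvement,
# an exploration floor, and a seeded random restart every 8th iteration.

gp_nll <- function(theta, u, y, noise) {
  ell <- exp(theta[1]); sf2 <- exp(theta[2])
  n <- length(u)
  K <- sf2 * exp(-0.5 * outer(u, u, "-")^2 / ell^2) + diag(noise + 1e-10, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  as.numeric(0.5 * sum(y * alpha) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi))
}

gp_fit <- function(u, y, noise) {
  mu <- mean(y)
  yc <- y - mu
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0) sy <- 1
  span <- max(diff(range(u)), 1e-3)
  best <- NULL
  for (ell0 in c(span / 4, span)) {
    o <- stats::optim(c(log(ell0), log(sy^2 + 1e-12)), gp_nll,
                      u = u, y = yc, noise = noise, method = "L-BFGS-B",
                      lower = c(log(span / 50), log(1e-12)),
                      upper = c(log(5 * span), log(100 * sy^2 + 1)))
    if (is.null(best) || o$value < best$value) best <- o
  }
  ell <- exp(best$par[1]); sf2 <- exp(best$par[2])
  K <- sf2 * exp(-0.5 * outer(u, u, "-")^2 / ell^2) + diag(noise + 1e-10, length(u))
  ch <- chol(K)
  alpha <- backsolve(ch, forwardsolve(t(ch), yc))
  list(u = u, mu = mu, ell = ell, sf2 = sf2, chol = ch, alpha = alpha)
}

gp_predict <- function(fit, ustar) {
  ks <- fit$sf2 * exp(-0.5 * outer(ustar, fit$u, "-")^2 / fit$ell^2)
  mean_p <- fit$mu + as.numeric(ks %*% fit$alpha)
  v <- forwardsolve(t(fit$chol), t(ks))
  var_p <- pmax(fit$sf2 - colSums(v^2), 0)
  list(mean = mean_p, sd = sqrt(var_p))
}

expected_improvement <- function(pred, y_best, xi = 0.01) {
  imp <- y_best - pred$mean - xi
  z <- ifelse(pred$sd > 0, imp / pred$sd, 0)
  ei <- ifelse(pred$sd > 0, imp * stats::pnorm(z) + pred$sd * stats::dnorm(z),
               pmax(imp, 0))
  ei
}

#' Minimise a 1-D objective by Bayesian optimisation
#'
#' @param objective function of a scalar `u` (here `u = log10(C)`)
#'   returning a finite value.
#' @param bounds search interval (default `c(-6, 6)`).
#' @param max_evals evaluation budget (default 30).
#' @param seed integer seed controlling the initial design and restart
#'   draws.
#' @param n_init initial quasi-random (stratified Latin-hypercube) points
#'   (default 4).
#' @param xi exploration floor in the expected-improvement acquisition
#'   (default 0.01).
#' @param restart_every every this-many iterations the next point is a
#'   seeded uniform draw instead of the acquisition argmax (default 8),
#'   approximating the extra exploration of the "expected improvement plus"
#'   family.
#' @return object of class `sdr_opt_trace`: list with `evaluated_points`,
#'   `objective_values`, `best_point`, `best_objective`, `seed`.
#' @export
optimize_1d <- function(objective, bounds = c(-6, 6), max_evals = 30,
                        seed = 0, n_init = 4, xi = 0.01, restart_every = 8) {
  stopifnot(length(bounds) == 2, bounds[1] < bounds[2])
  grid <- seq(bounds[1], bounds[2], by = 0.01)
  evals_u <- numeric(0); evals_y <- numeric(0)
  eval_at <- function(u) {
    y <- objective(u)
    if (!is.finite(y)) stopf("objective returned a non-finite value at u = %g", u)
    evals_u <<- c(evals_u, u); evals_y <<- c(evals_y, y)
    y
  }
  init <- with_seed(derive_seed(seed, "bo_init"), {
    edges <- seq(bounds[1], bounds[2], length.out = n_init + 1)
    runif(n_init, edges[-(n_init + 1)], edges[-1])
  })
  for (u in init) eval_at(u)

  it <- 0L
  while (length(evals_u) < max_evals) {
    it <- it + 1L
    u_next <- if (restart_every > 0 && it %% restart_every == 0) {
      with_seed(derive_seed(seed, "bo_restart", it),
                runif(1, bounds[1], bounds[2]))
    } else {
      noise <- 1e-6 * max(stats::var(evals_y), 1e-12)
      fit <- gp_fit(evals_u, evals_y, noise)
      pred <- gp_predict(fit, grid)
      ei <- expected_improvement(pred, min(evals_y), xi)
      cand <- grid[which.max(ei)]
      if (min(abs(cand - evals_u)) < 1e-9 || max(ei) <= 0) {
        # acquisition collapsed onto a known point: take the most
        # uncertain grid point instead
        grid[which.max(pred$sd + 1e-12 * abs(grid - mean(bounds)))]
      } else cand
    }
    if (min(abs(u_next - evals_u)) < 1e-9) {
      u_next <- with_seed(derive_seed(seed, "bo_dedup", it),
                          runif(1, bounds[1], bounds[2]))
    }
    eval_at(u_next)
  }
  best <- which.min(evals_y)
  structure(list(evaluated_points = evals_u, objective_values = evals_y,
                 best_point = evals_u[best], best_objective = evals_y[best],
                 seed = seed),
            class = "sdr_opt_trace")
}

#' Select the SVM box constraint for one subject
#'
#' Runs [optimize_1d()] on the 10-fold cross-validation loss
#' `1 - mean(fold accuracies)` as a function of `log10(C)` over
#' `\[1e-6, 1e+6\]` with at most 30 objective evaluations. The selected C is
#' then reused for every fold of the final reported cross-validation.
#'
#' @param table `sdr_feature_table` for one subject.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @param bounds log10 bounds (default `c(-6, 6)`).
#' @param max_evals evaluation budget (default 30).
#' @param ... passed to [cross_validate()].
#' @return list with `C` (the selected box constraint) and `trace`.
#' @export
select_box_constraint <- function(table, k = 10, seed = 0,
                                  bounds = c(-6, 6), max_evals = 30, ...) {
  obj <- function(u) {
    res <- cross_validate(table, C = 10^u, k = k, ...)
    1 - mean(res$fold_accuracies)
  }
  trace <- optimize_1d(obj, bounds = bounds, max_evals = max_evals, seed = seed)
  list(C = 10^trace$best_point, trace = trace)
}
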