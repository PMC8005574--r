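# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the code paths they check.

# Brute-force signed-rank enumeration over bitmasks (independent of the
# package's expand.grid-based enumeration): distribution of the
# positive-rank sum over all 2^n sign assignments of the |d| mid-ranks.
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  total <- 2^n
  stats_all <- numeric(total)
  for (m in 0:(total - 1)) {
    v <- 0
    for (i in seq_len(n)) if (bitwAnd(m, bitwShiftL(1L, i - 1L)) != 0) v <- v + r[i]
    stats_all[m + 1] <- v
  }
  min(1, 2 * min(mean(stats_all <= v_obs), mean(stats_all >= v_obs)))
}

# Literal step-up definition of Benjamini-Hochberg rejections.
oracle_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  k <- 0
  for (i in seq_len(m)) if (p[ord[i]] <= i / m * q) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Friedman chi-square with tie correction, computed from first principles
# (explicit rank matrix, textbook tie-corrected form).
oracle_friedman_stat <- function(X) {
  n <- nrow(X); k <- ncol(X)
  R <- t(apply(X, 1, rank))
  num <- (k - 1) * sum((colSums(R) - n * (k + 1) / 2)^2)
  den <- sum(R^2) - n * k * (k + 1)^2 / 4
  num / den
}

# Dual objective e'a - 0.5 a'Qa of a multiplier vector. At the optimum it
# equals the primal hinge objective, and unlike the primal it is well
# conditioned at large C (the primal amplifies O(eps) margin differences of
# on-margin support vectors by C), so solver agreement is assessed here.
svm_dual_objective <- function(alpha, X, y) {
  v <- alpha * y
  sum(alpha) - 0.5 * sum((as.matrix(X) %*% crossprod(as.matrix(X), v)) * v)
}

# Batched external QP oracle: solve n_inst linear C-SVMs with sklearn
# (libsvm) and return the dual objective and training predictions.
# One python process for the whole batch.
oracle_svm_batch <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  jsonlite::write_json(lapply(instances, function(inst) {
    list(X = inst$X, y = inst$y, C = inst$C)
  }), infile, digits = NA, auto_unbox = TRUE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import json, sys",
    "import numpy as np",
    "from sklearn.svm import SVC",
    sprintf("insts = json.load(open('%s'))", infile),
    "out = []",
    "for inst in insts:",
    "    X = np.asarray(inst['X'], dtype=float)",
    "    y = np.asarray(inst['y'], dtype=float)",
    "    C = float(inst['C'])",
    "    m = SVC(kernel='linear', C=C, tol=1e-10).fit(X, y)",
    "    alpha = np.zeros(len(y)); alpha[m.support_] = m.dual_coef_[0] * y[m.support_]",
    "    v = alpha * y",
    "    dual = float(alpha.sum() - 0.5 * v @ (X @ X.T) @ v)",
    "    pred = np.sign(X @ m.coef_[0] + m.intercept_[0])",
    "    out.append({'objective': dual, 'pred': pred.tolist()})",
    sprintf("json.dump(out, open('%s', 'w'))", outfile)
  ), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  if (!file.exists(outfile))
    stop("python sklearn oracle failed: ", paste(status, collapse = "\n"))
  lapply(jsonlite::read_json(outfile, simplifyVector = FALSE), function(o) {
    list(objective = o$objective, pred = unlist(o$pred))
  })
}

# Gaussian feature table: fast stand-in for the spectral pipeline when the
# decoder alone is under test. `shift` is added to ON samples.
make_gaussian_table <- function(n_per_class, shift = c(0, 0, 0, 0), seed = 1,
                                sd = 1) {
  set.seed(seed)
  n_feat <- length(shift)
  mk <- function(cond, delta) {
    m <- matrix(rnorm(n_per_class * n_feat, sd = sd), n_per_class, n_feat)
    m <- sweep(m, 2, delta, "+")
    df <- data.frame(subject_id = "T", condition = cond, hemisphere = "left",
                     snippet_index = seq_len(n_per_class))
    df[paste0("bp_", seq_len(n_feat))] <- m
    df
  }
  tab <- rbind(mk("OFF", rep(0, n_feat)), mk("ON", shift))
  structure(tab, class = c("sdr_feature_table", "data.frame"))
}

# Full signal-level subject fixture (both conditions, both hemispheres).
make_subject_recordings <- function(spec, duration_s = 30, fs = 1000, seed = 1) {
  recs <- list()
  for (cond in c("OFF", "ON")) for (hemi in c("left", "right")) {
    recs[[paste(cond, hemi, sep = "_")]] <- generate_source_signal(
      spec, cond, hemi, duration_s, fs,
      seed = derive_seed(seed, spec$subject_id, cond, hemi))
  }
  recs
}

# 33-item rating helper: constant score everywhere.
make_constant_ratings <- function(score, subject = "X", condition = "OFF") {
  structure_items <- sdrdecode::default_factor_structure()
  codes <- names(structure_items$assignment)
  item_ratings(subject, condition, stats::setNames(rep(score, 33), codes))
}
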