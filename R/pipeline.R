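# End-to-end orchestration: simulate (or load) -> spectral features ->
# per-subject box-constraint search -> decode -> clinical factor scores ->
# statistics -> report. Every stage derives its random stream from the one
# top-level seed, so a fixed config reproduces all numbers exactly.

#' Assemble a pipeline configuration
#'
#' Defaults reproduce the reference analysis settings: 20 subjects, 180 s
#' per condition per hemisphere at 1 kHz, 5 s epochs and snippets, order-18
#' Butterworth lowpass at 48 Hz, 1 s Hamming Welch windows on a 0.5 Hz
#' grid, 10 folds, global standardization, deterministic tail balancing,
#' and a 30-evaluation box-constraint search over \[1e-6, 1e+6\].
#'
#' @param cohort a [cohort_spec()] (default: 20-subject null cohort,
#'   seed 0).
#' @param k cross-validation folds.
#' @param standardize_scope `"global"` or `"per_fold"`.
#' @param balance_mode `"tail"` or `"random"`.
#' @param hemisphere_mode `"samples"` or `"features"`.
#' @param optimizer list of `bounds`, `max_evals`; set `optimize_C = FALSE`
#'   to skip the search and use `fixed_C`.
#' @param optimize_C logical (default TRUE).
#' @param fixed_C box constraint used when `optimize_C = FALSE`.
#' @param alpha significance level for the statistics battery.
#' @param out_dir optional directory; when given, every stage writes its
#'   artifact there.
#' @return list of class `sdr_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), k = 10,
                            standardize_scope = "global",
                            balance_mode = "tail",
                            hemisphere_mode = "samples",
                            optimizer = list(bounds = c(-6, 6), max_evals = 30),
                            optimize_C = TRUE, fixed_C = 1,
                            alpha = 0.05, out_dir = NULL) {
  structure(list(cohort = cohort, k = k,
                 standardize_scope = standardize_scope,
                 balance_mode = balance_mode,
                 hemisphere_mode = hemisphere_mode,
                 optimizer = optimizer, optimize_C = optimize_C,
                 fixed_C = fixed_C, alpha = alpha, out_dir = out_dir),
            class = "sdr_pipeline_config")
}

#' Serialise a pipeline configuration to JSON
#'
#' The persisted config fully determines a run, so serialise-parse-serialise
#' is idempotent.
#'
#' @param config an [pipeline_config()].
#' @param path output path.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "sdr_pipeline_config"))
  x <- unclass(config)
  x$cohort <- unclass(x$cohort)
  x$cohort$subject_specs <- if (!is.null(x$cohort$subject_specs))
    lapply(x$cohort$subject_specs, unclass) else NULL
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a pipeline configuration from JSON
#' @param path JSON written by [write_config_json()].
#' @return an `sdr_pipeline_config`.
#' @export
read_config_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  specs <- if (!is.null(x$cohort$subject_specs))
    lapply(x$cohort$subject_specs, function(s) do.call(subject_spec, s))
  cohort <- cohort_spec(
    n_subjects = x$cohort$n_subjects, duration_s = x$cohort$duration_s,
    sampling_rate_hz = x$cohort$sampling_rate_hz, seed = x$cohort$seed,
    subject_specs = specs, effect_sd = x$cohort$effect_sd,
    effect_range = x$cohort$effect_range, coupling = x$cohort$coupling,
    artifact_burst_rate = x$cohort$artifact_burst_rate)
  pipeline_config(cohort = cohort, k = x$k,
                  standardize_scope = x$standardize_scope,
                  balance_mode = x$balance_mode,
                  hemisphere_mode = x$hemisphere_mode,
                  optimizer = x$optimizer, optimize_C = x$optimize_C,
                  fixed_C = x$fixed_C, alpha = x$alpha,
                  out_dir = x$out_dir)
}

decode_subject <- function(tab, config, seed_subject) {
  if (config$optimize_C) {
    sel <- select_box_constraint(tab, k = config$k, seed = seed_subject,
                                 bounds = config$optimizer$bounds,
                                 max_evals = config$optimizer$max_evals,
                                 standardize_scope = config$standardize_scope,
                                 balance_mode = config$balance_mode)
    C <- sel$C
  } else {
    sel <- NULL
    C <- config$fixed_C
  }
  res <- cross_validate(tab, C = C, k = config$k,
                        standardize_scope = config$standardize_scope,
                        balance_mode = config$balance_mode)
  list(result = res, trace = sel$trace)
}

#' Run the full analysis pipeline
#'
#' @param config an [pipeline_config()] object.
#' @param cohort_data optional pre-generated output of [generate_cohort()];
#'   when `NULL` the cohort in `config` is generated.
#' @return list of class `sdr_report` with elements `features` (per-subject
#'   feature tables), `decoding` (per-subject `sdr_decode_result`),
#'   `accuracies`, `weight_profiles`, `factor_scores`, `changes`
#'   (subjects x 7), `stats` (wilcoxon/friedman/posthoc/spearman/
#'   regression), `config`, `ground_truth`.
#' @export
run_full_pipeline <- function(config = pipeline_config(), cohort_data = NULL) {
  stopifnot(inherits(config, "sdr_pipeline_config"))
  cohort <- config$cohort
  data <- cohort_data %||% generate_cohort(cohort)
  specs <- data$subject_specs
  ids <- vapply(specs, function(s) s$subject_id, character(1))

  features <- list(); decoding <- list(); traces <- list()
  scores_off <- list(); scores_on <- list()
  for (id in ids) {
    recs <- data$recordings[grepl(paste0("^", id, "_"), names(data$recordings))]
    tab <- tryCatch(
      build_feature_table(recs, hemisphere_mode = config$hemisphere_mode),
      error = function(e) stopf("stage 'features', subject %s: %s", id, conditionMessage(e)))
    features[[id]] <- tab
    dec <- tryCatch(
      decode_subject(tab, config, derive_seed(cohort$seed, "decode", id)),
      error = function(e) stopf("stage 'decode', subject %s: %s", id, conditionMessage(e)))
    decoding[[id]] <- dec$result
    traces[[id]] <- dec$trace
    scores_off[[id]] <- factor_scores(data$ratings[[paste0(id, "_OFF")]])
    scores_on[[id]] <- factor_scores(data$ratings[[paste0(id, "_ON")]])
  }

  accuracies <- vapply(decoding, function(r) r$median_accuracy, numeric(1))
  profiles <- lapply(decoding, weight_profile)
  changes <- t(vapply(ids, function(id) sdr_change(scores_off[[id]], scores_on[[id]]),
                      numeric(7)))
  colnames(changes) <- paste0("factor_", 1:7)

  off_w <- t(vapply(scores_off, function(s) s$weighted_averages, numeric(7)))
  on_w <- t(vapply(scores_on, function(s) s$weighted_averages, numeric(7)))

  # per-factor paired OFF vs ON tests, Bonferroni over the 7 factors
  wil <- lapply(1:7, function(f) {
    tryCatch(wilcoxon_signed_rank(off_w[, f], on_w[, f]),
             error = function(e) list(statistic = NA_real_, p_value = NA_real_,
                                      n_effective = 0L, method = conditionMessage(e)))
  })
  raw_p <- vapply(wil, function(w) w$p_value, numeric(1))
  adj_p <- ifelse(is.na(raw_p), NA_real_, bonferroni(ifelse(is.na(raw_p), 1, raw_p), m = 7))

  fried <- friedman_test(changes)

  # post hoc: all 21 factor pairs compared on their changes, BH corrected
  pairs <- utils::combn(7, 2)
  posthoc_p <- apply(pairs, 2, function(pr) {
    tryCatch(wilcoxon_signed_rank(changes[, pr[1]], changes[, pr[2]])$p_value,
             error = function(e) NA_real_)
  })
  bh <- benjamini_hochberg(ifelse(is.na(posthoc_p), 1, posthoc_p), q = config$alpha)

  # cohort-level statistics need enough subjects; small test cohorts get NULL
  spear <- tryCatch(spearman_matrix(changes), error = function(e) NULL)
  reg <- tryCatch(accuracy_sdr_regression(accuracies, changes),
                  error = function(e) NULL)

  report <- structure(list(
    features = features, decoding = decoding, opt_traces = traces,
    accuracies = accuracies, weight_profiles = profiles,
    factor_scores = list(off = off_w, on = on_w), changes = changes,
    stats = list(
      wilcoxon = data.frame(factor = 1:7,
                            statistic = vapply(wil, function(w) w$statistic, numeric(1)),
                            p_raw = raw_p, p_bonferroni = adj_p),
      friedman = fried,
      posthoc = data.frame(factor_a = pairs[1, ], factor_b = pairs[2, ],
                           p_raw = posthoc_p, p_bh = bh$adjusted,
                           rejected = bh$rejected),
      bh_critical_p = bh$critical_p,
      spearman = spear, regression = reg),
    ground_truth = data$ground_truth, config = config
  ), class = "sdr_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Grand median accuracy of a report
#' @param report an `sdr_report`.
#' @return median over subjects of the per-subject median fold accuracies.
#' @export
grand_median_accuracy <- function(report) {
  stats::median(report$accuracies)
}

#' Write all pipeline artifacts to a directory
#'
#' Per-subject feature tables and decode results, a cohort accuracy/weight
#' CSV, the statistics CSVs and a Markdown summary.
#'
#' @param report `sdr_report`.
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(report$features))
    write_feature_table_csv(report$features[[id]],
                            file.path(dir, sprintf("features_%s.csv", id)))
  for (id in names(report$decoding))
    write_decode_result_json(report$decoding[[id]],
                             file.path(dir, sprintf("decode_%s.json", id)))
  cohort_df <- data.frame(
    subject_id = names(report$accuracies),
    median_accuracy = as.numeric(report$accuracies),
    t(vapply(report$weight_profiles, function(p) p$mean_weight,
             numeric(nrow(report$weight_profiles[[1]]))))
  )
  names(cohort_df)[-(1:2)] <- paste0("w_", report$weight_profiles[[1]]$band)
  utils::write.csv(cohort_df, file.path(dir, "cohort_accuracy_weights.csv"),
                   row.names = FALSE)
  ch <- report$changes
  ch_long <- data.frame(subject_id = rep(rownames(ch) %||% names(report$accuracies),
                                         times = ncol(ch)),
                        factor = rep(1:7, each = nrow(ch)),
                        change = as.numeric(ch))
  utils::write.csv(ch_long, file.path(dir, "factor_changes.csv"), row.names = FALSE)
  utils::write.csv(report$stats$wilcoxon, file.path(dir, "stats_wilcoxon.csv"),
                   row.names = FALSE)
  utils::write.csv(report$stats$posthoc, file.path(dir, "stats_posthoc.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    friedman = report$stats$friedman,
    bh_critical_p = report$stats$bh_critical_p,
    regression = lapply(report$stats$regression, function(r)
      r[c("slope", "intercept", "r_squared", "p_value", "p_adjusted")]),
    grand_median_accuracy = grand_median_accuracy(report)
  ), file.path(dir, "stats_summary.json"), auto_unbox = TRUE, digits = NA)
  writeLines(render_report_md(report), file.path(dir, "report.md"))
  write_config_json(report$config, file.path(dir, "config.json"))
  invisible(dir)
}

render_report_md <- function(report) {
  acc <- report$accuracies
  c("# SDR decoding report",
    "",
    sprintf("Subjects: %d; grand median accuracy: %.3f",
            length(acc), grand_median_accuracy(report)),
    "",
    "## Per-subject decoding",
    "",
    "| subject | median accuracy | C | ROC area |",
    "|---|---|---|---|",
    vapply(names(report$decoding), function(id) {
      r <- report$decoding[[id]]
      sprintf("| %s | %.3f | %.3g | %.3f |", id, r$median_accuracy,
              r$box_constraint, r$roc$area)
    }, character(1)),
    "",
    "## Clinical statistics",
    "",
    sprintf("Friedman chi-square = %.3f, df = %d, p = %.3g",
            report$stats$friedman$statistic, report$stats$friedman$df,
            report$stats$friedman$p_value),
    sprintf("Benjamini-Hochberg critical p: %s",
            format(report$stats$bh_critical_p)),
    "",
    "| factor | Wilcoxon p (raw) | p (Bonferroni) | regression R^2 | slope p |",
    "|---|---|---|---|---|",
    vapply(1:7, function(f) {
      reg <- report$stats$regression[[f]]
      sprintf("| %d | %.3g | %.3g | %s | %s |", f,
              report$stats$wilcoxon$p_raw[f], report$stats$wilcoxon$p_bonferroni[f],
              if (is.null(reg)) "-" else sprintf("%.3f", reg$r_squared),
              if (is.null(reg)) "-" else sprintf("%.3g", reg$p_value))
    }, character(1)))
}

#' @export
print.sdr_report <- function(x, ...) {
  cat(render_report_md(x), sep = "\n")
  invisible(x)
}
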