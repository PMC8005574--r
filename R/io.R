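# Plain-text exchange formats. Recordings travel as per-recording CSV
# (sample column plus a header row of metadata columns), ratings and
# feature tables as tidy CSV, ground truth and decode results as JSON.

#' Write cohort recordings to CSV files
#'
#' One file per subject x condition x hemisphere named
#' `<subject>_<condition>_<hemisphere>.csv` with columns
#' `subject_id, condition, hemisphere, sampling_rate_hz, sample`.
#'
#' @param recordings list of `sdr_recording` objects.
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_recordings_csv <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(recordings, function(r) {
    path <- file.path(dir, sprintf("%s_%s_%s.csv", r$subject_id, r$condition,
                                   r$hemisphere))
    df <- data.frame(subject_id = r$subject_id, condition = r$condition,
                     hemisphere = r$hemisphere,
                     sampling_rate_hz = r$sampling_rate_hz,
                     sample = r$samples)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }, character(1))
  invisible(paths)
}

#' Read recordings written by [write_recordings_csv()]
#' @param paths CSV file paths.
#' @return list of `sdr_recording` objects.
#' @export
read_recordings_csv <- function(paths) {
  lapply(paths, function(p) {
    df <- utils::read.csv(p, stringsAsFactors = FALSE)
    need <- c("subject_id", "condition", "hemisphere", "sampling_rate_hz", "sample")
    miss <- setdiff(need, names(df))
    if (length(miss)) stopf("%s: missing column(s) %s", p, paste(miss, collapse = ", "))
    structure(list(subject_id = as.character(df$subject_id[1]),
                   condition = df$condition[1], hemisphere = df$hemisphere[1],
                   samples = df$sample,
                   sampling_rate_hz = df$sampling_rate_hz[1]),
              class = "sdr_recording")
  })
}

#' Write item ratings to a tidy CSV
#'
#' Columns: `subject_id, condition, item_code, score`.
#' @param ratings list of `sdr_item_ratings`.
#' @param path output CSV path.
#' @export
write_ratings_csv <- function(ratings, path) {
  df <- do.call(rbind, lapply(ratings, function(r) {
    data.frame(subject_id = r$subject_id, condition = r$condition,
               item_code = names(r$scores), score = as.integer(r$scores))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read item ratings from a tidy CSV
#' @param path CSV with columns `subject_id, condition, item_code, score`.
#' @return list of `sdr_item_ratings`, one per subject x condition.
#' @export
read_ratings_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "item_code", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("ratings CSV missing column(s): %s", paste(miss, collapse = ", "))
  out <- list()
  for (key in unique(paste(df$subject_id, df$condition, sep = "_"))) {
    sub <- df[paste(df$subject_id, df$condition, sep = "_") == key, ]
    scores <- stats::setNames(sub$score, sub$item_code)
    out[[key]] <- item_ratings(sub$subject_id[1], sub$condition[1], scores)
  }
  out
}

#' Write a feature table to CSV
#' @param table `sdr_feature_table`.
#' @param path output path.
#' @export
write_feature_table_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table from CSV
#' @param path CSV with columns `subject_id, condition, hemisphere,
#'   snippet_index` and `bp_*` feature columns.
#' @return `sdr_feature_table`.
#' @export
read_feature_table_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "hemisphere", "snippet_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("feature CSV missing column(s): %s", paste(miss, collapse = ", "))
  if (!length(grep("^bp_", names(df)))) stopf("feature CSV has no bp_* columns")
  bad <- setdiff(unique(df$condition), SDR_CONDITIONS)
  if (length(bad)) stopf("feature CSV has unknown condition(s): %s", paste(bad, collapse = ", "))
  structure(df, class = c("sdr_feature_table", "data.frame"))
}

#' Serialise a decode result to JSON
#' @param result `sdr_decode_result`.
#' @param path output path.
#' @export
write_decode_result_json <- function(result, path) {
  jsonlite::write_json(list(
    subject_id = result$subject_id,
    fold_accuracies = result$fold_accuracies,
    median_accuracy = result$median_accuracy,
    box_constraint = result$box_constraint,
    n_samples_per_class = result$n_samples_per_class,
    fold_weight_vectors = result$fold_weight_vectors,
    roc = result$roc[c("fpr", "tpr", "area")]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load externally produced cohort-level tables for the statistics battery
#'
#' Routes user-supplied per-subject accuracies and factor-change tables
#' (same schemas this package writes) straight into the statistics stage,
#' bypassing simulation and decoding.
#'
#' @param accuracy_csv CSV with columns `subject_id, median_accuracy`.
#' @param changes_csv CSV with columns `subject_id, factor, change`
#'   (factor in 1..7).
#' @return list with `accuracies` (named numeric) and `changes`
#'   (subjects x 7 matrix), rows aligned on `subject_id`.
#' @export
load_external_tables <- function(accuracy_csv, changes_csv) {
  acc <- utils::read.csv(accuracy_csv, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "median_accuracy"), names(acc))
  if (length(miss)) stopf("accuracy CSV missing column(s): %s", paste(miss, collapse = ", "))
  ch <- utils::read.csv(changes_csv, stringsAsFactors = FALSE)
  miss <- setdiff(c("subject_id", "factor", "change"), names(ch))
  if (length(miss)) stopf("changes CSV missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(ch$factor %in% 1:7)) stopf("'factor' must be in 1..7")
  ids <- intersect(acc$subject_id, unique(ch$subject_id))
  if (!length(ids)) stopf("no shared subject_id between the two tables")
  M <- matrix(NA_real_, length(ids), 7,
              dimnames = list(ids, paste0("factor_", 1:7)))
  for (r in seq_len(nrow(ch))) {
    if (ch$subject_id[r] %in% ids) M[as.character(ch$subject_id[r]), ch$factor[r]] <- ch$change[r]
  }
  if (any(is.na(M))) stopf("changes table is missing factor entries for some subjects")
  list(accuracies = stats::setNames(acc$median_accuracy[match(ids, acc$subject_id)], ids),
       changes = M)
}
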