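# MDS-UPDRS Part III motor-factor scoring. The 33 motor-exam items are
# partitioned into 7 empirically derived factors; each factor is summarised
# both as a raw sum and as a weighted average on the 0-4 item scale.

MDS_UPDRS_ITEMS <- c(
  "3.1", "3.2",
  paste0("3.3", letters[1:5]),
  paste0("3.4", letters[1:2]), paste0("3.5", letters[1:2]),
  paste0("3.6", letters[1:2]), paste0("3.7", letters[1:2]),
  paste0("3.8", letters[1:2]),
  "3.9", "3.10", "3.11", "3.12", "3.13", "3.14",
  paste0("3.15", letters[1:2]), paste0("3.16", letters[1:2]),
  paste0("3.17", letters[1:5]), "3.18"
)

SDR_FACTOR_NAMES <- c(
  "midline function", "rest tremor", "rigidity",
  "bradykinesia right upper extremity", "bradykinesia left upper extremity",
  "postural and kinetic tremors", "lower limb bradykinesia"
)

#' MDS-UPDRS Part III item ratings for one subject and condition
#'
#' @param subject_id identifier.
#' @param condition `"OFF"` or `"ON"`.
#' @param scores named integer vector covering all 33 Part III item codes
#'   (`3.1` ... `3.18`, with lettered sub-items), each in 0-4.
#' @return object of class `sdr_item_ratings`.
#' @export
item_ratings <- function(subject_id, condition, scores) {
  condition <- match.arg(condition, SDR_CONDITIONS)
  missing <- setdiff(MDS_UPDRS_ITEMS, names(scores))
  if (length(missing))
    stopf("missing item(s): %s", paste(missing, collapse = ", "))
  extra <- setdiff(names(scores), MDS_UPDRS_ITEMS)
  if (length(extra))
    stopf("unknown item(s): %s", paste(extra, collapse = ", "))
  scores <- scores[MDS_UPDRS_ITEMS]
  if (any(!is.finite(scores)) || any(scores != round(scores)) ||
      any(scores < 0) || any(scores > 4))
    stopf("all item scores must be integers in 0-4")
  structure(list(subject_id = as.character(subject_id), condition = condition,
                 scores = as.integer(round(scores)) |> stats::setNames(MDS_UPDRS_ITEMS)),
            class = "sdr_item_ratings")
}

#' The canonical 7-factor structure of the MDS-UPDRS motor exam
#'
#' Factors: (1) midline function, (2) rest tremor, (3) rigidity,
#' (4) right upper-extremity bradykinesia, (5) left upper-extremity
#' bradykinesia, (6) postural and kinetic tremors, (7) lower-limb
#' bradykinesia, containing 8, 6, 5, 3, 3, 4 and 4 items respectively.
#' Default per-item weights are uniform; published factor loadings can be
#' supplied through `weights_csv` (columns `item_code,weight`).
#'
#' @param weights_csv optional path to a CSV of per-item weights.
#' @return object of class `sdr_factor_structure`: list with `assignment`
#'   (named integer vector item -> factor), `weights` (named numeric) and
#'   `factor_names`.
#' @export
default_factor_structure <- function(weights_csv = NULL) {
  assignment <- c(
    "3.1" = 1, "3.2" = 1, "3.9" = 1, "3.10" = 1, "3.11" = 1, "3.12" = 1,
    "3.13" = 1, "3.14" = 1,
    "3.17a" = 2, "3.17b" = 2, "3.17c" = 2, "3.17d" = 2, "3.17e" = 2, "3.18" = 2,
    "3.3a" = 3, "3.3b" = 3, "3.3c" = 3, "3.3d" = 3, "3.3e" = 3,
    "3.4a" = 4, "3.5a" = 4, "3.6a" = 4,
    "3.4b" = 5, "3.5b" = 5, "3.6b" = 5,
    "3.15a" = 6, "3.15b" = 6, "3.16a" = 6, "3.16b" = 6,
    "3.7a" = 7, "3.7b" = 7, "3.8a" = 7, "3.8b" = 7
  )
  assignment <- assignment[MDS_UPDRS_ITEMS]
  weights <- stats::setNames(rep(1, length(assignment)), names(assignment))
  if (!is.null(weights_csv)) {
    w <- utils::read.csv(weights_csv, stringsAsFactors = FALSE)
    if (!all(c("item_code", "weight") %in% names(w)))
      stopf("weights CSV must have columns 'item_code' and 'weight'")
    unknown <- setdiff(w$item_code, MDS_UPDRS_ITEMS)
    if (length(unknown)) stopf("unknown item code(s) in weights CSV: %s",
                               paste(unknown, collapse = ", "))
    if (any(w$weight <= 0)) stopf("weights must be positive")
    weights[w$item_code] <- w$weight
  }
  structure(list(assignment = assignment, weights = weights,
                 factor_names = SDR_FACTOR_NAMES),
            class = "sdr_factor_structure")
}

#' Motor factor scores from item ratings
#'
#' Raw sums and weighted averages per factor. Weighted averages stay on the
#' 0-4 item scale: `sum(w_i * s_i) / sum(w_i)` over the items of each
#' factor.
#'
#' @param ratings an [item_ratings()] object.
#' @param structure a factor structure from [default_factor_structure()].
#' @return object of class `sdr_factor_scores`: list with `raw_sums` and
#'   `weighted_averages` (length-7 numeric each) plus subject metadata.
#' @export
factor_scores <- function(ratings, structure = default_factor_structure()) {
  stopifnot(inherits(ratings, "sdr_item_ratings"),
            inherits(structure, "sdr_factor_structure"))
  missing <- setdiff(names(structure$assignment), names(ratings$scores))
  if (length(missing))
    stopf("ratings are missing item(s): %s", paste(missing, collapse = ", "))
  raw <- numeric(7); wavg <- numeric(7)
  for (f in 1:7) {
    items <- names(structure$assignment)[structure$assignment == f]
    s <- as.numeric(ratings$scores[items])
    w <- structure$weights[items]
    raw[f] <- sum(s)
    wavg[f] <- sum(w * s) / sum(w)
  }
  base::structure(list(subject_id = ratings$subject_id,
                       condition = ratings$condition,
                       raw_sums = raw, weighted_averages = wavg),
                  class = "sdr_factor_scores")
}

#' Short-duration response: OFF minus ON factor-score change
#'
#' Positive values indicate improvement with medication.
#'
#' @param off,on [factor_scores()] for the two conditions of one subject.
#' @return length-7 numeric of weighted-average changes.
#' @export
sdr_change <- function(off, on) {
  stopifnot(inherits(off, "sdr_factor_scores"), inherits(on, "sdr_factor_scores"))
  off$weighted_averages - on$weighted_averages
}
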