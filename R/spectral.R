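# Spectral feature extraction: per-hemisphere signals become per-snippet
# band-power feature tables. Stage order matters: epoch rejection runs on
# the raw signal (its 50-330 Hz score band would not survive the lowpass),
# then the 48 Hz lowpass, 5 s / 50%-overlap snippeting, per-snippet
# z-normalisation, Welch spectra on a 0.5 Hz grid, and band integration.

#' Reject high-frequency-contaminated epochs
#'
#' The signal is cut into non-overlapping epochs and each epoch is scored by
#' its mean periodogram power in a high-frequency band (muscle and spike
#' artifacts live there). Epochs scoring more than `z_threshold` standard
#' deviations above the mean score are rejected.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param band scoring band in Hz (default `c(50, 330)`); the upper edge is
#'   clipped to Nyquist with a warning when `fs < 660`.
#' @param z_threshold rejection threshold in standard deviations
#'   (default 1.5).
#' @return object of class `sdr_epoch_mask`: list with `epoch_starts`
#'   (sample indices), `keep` (logical) and `rejection_scores`.
#' @export
reject_noisy_epochs <- function(signal, fs, epoch_len_s = 5,
                                band = c(50, 330), z_threshold = 1.5) {
  n_epoch <- round(epoch_len_s * fs)
  if (length(signal) < n_epoch)
    stopf("signal (%d samples) is shorter than one %g s epoch", length(signal), epoch_len_s)
  if (band[2] > fs / 2) {
    warnf("rejection band upper edge %g Hz clipped to Nyquist %g Hz", band[2], fs / 2)
    band[2] <- fs / 2
  }
  starts <- seq(1L, length(signal) - n_epoch + 1L, by = n_epoch)
  scores <- vapply(starts, function(s0) {
    periodogram_band_power(signal[s0:(s0 + n_epoch - 1L)], fs, band)
  }, numeric(1))
  s <- if (length(scores) > 1) stats::sd(scores) else 0
  keep <- scores <= mean(scores) + z_threshold * s
  structure(list(epoch_starts = starts, keep = keep, rejection_scores = scores),
            class = "sdr_epoch_mask")
}

#' Order-18 Butterworth lowpass
#'
#' Single-pass (causal) filtering through second-order sections. The
#' magnitude response follows `|H(f)|^2 = 1 / (1 + (f/fc)^(2*order))` at the
#' prewarped design frequencies.
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz (> 2 * `half_power_hz`).
#' @param order filter order (default 18).
#' @param half_power_hz -3 dB frequency in Hz (default 48).
#' @return filtered signal, same length.
#' @export
lowpass_filter <- function(signal, fs, order = 18, half_power_hz = 48) {
  if (fs <= 2 * half_power_hz)
    stopf("fs must exceed twice the half-power frequency (%g Hz)", half_power_hz)
  sos_filter(butter_sos(order, half_power_hz, fs, type = "low"), signal)
}

#' Cut a signal into fixed-length overlapping snippets
#'
#' @param signal numeric vector.
#' @param fs sampling rate in Hz.
#' @param snippet_len_s snippet length in seconds (default 5).
#' @param overlap fractional overlap (default 0.5, i.e. 2.5 s hop).
#' @return list of full-length snippets; a too-short signal yields an empty
#'   list with a warning so batch pipelines can skip rather than abort.
#' @export
segment_snippets <- function(signal, fs, snippet_len_s = 5, overlap = 0.5) {
  n_snip <- round(snippet_len_s * fs)
  if (length(signal) < n_snip) {
    warnf("signal (%d samples) shorter than one %g s snippet; returning none",
          length(signal), snippet_len_s)
    return(list())
  }
  hop <- round(n_snip * (1 - overlap))
  starts <- seq(1L, length(signal) - n_snip + 1L, by = hop)
  lapply(starts, function(s0) signal[s0:(s0 + n_snip - 1L)])
}

#' Z-normalise a snippet to zero mean and unit variance
#'
#' @param snippet numeric vector with positive variance.
#' @return normalised snippet.
#' @export
normalize_snippet <- function(snippet) {
  v <- stats::var(snippet)
  if (!is.finite(v) || v <= 0) stopf("cannot normalise a constant snippet")
  (snippet - mean(snippet)) / sqrt(v)
}

#' Average power spectra across vertices
#'
#' @param spectra list of `sdr_spectrum` objects on identical grids.
#' @return element-wise mean spectrum.
#' @export
average_vertex_spectra <- function(spectra) {
  if (!length(spectra)) stopf("no spectra to average")
  f0 <- spectra[[1]]$frequencies_hz
  for (sp in spectra) {
    if (length(sp$frequencies_hz) != length(f0) ||
        any(abs(sp$frequencies_hz - f0) > 1e-9))
      stopf("spectra are not on identical frequency grids")
  }
  new_spectrum(f0, rowMeans(vapply(spectra, function(sp) sp$power,
                                   numeric(length(f0)))))
}

#' Mean band power from a power spectrum
#'
#' Bands are half-open `[low, high)` so that the shared 13 Hz edge of the
#' 7-13 and 13-20 Hz bands is counted once; power is the mean (not sum) of
#' PSD bins, which is invariant to grid refinement.
#'
#' @param spectrum an `sdr_spectrum`.
#' @param bands list of length-2 band edges in Hz (default: the four
#'   analysis bands 7-13, 13-20, 20-30, 35-45).
#' @return numeric vector of one mean power per band.
#' @export
band_power <- function(spectrum, bands = SDR_BANDS) {
  f <- spectrum$frequencies_hz
  vapply(bands, function(b) {
    if (b[1] < min(f) || b[2] > max(f) + 1e-9)
      stopf("band [%g, %g] Hz lies outside the spectrum grid", b[1], b[2])
    sel <- f >= b[1] & f < b[2]
    if (!any(sel)) stopf("band [%g, %g] Hz contains no grid points", b[1], b[2])
    mean(spectrum$power[sel])
  }, numeric(1))
}

#' Build the per-snippet band-power feature table for one subject
#'
#' Applies reject -> lowpass -> segment -> normalise -> Welch -> band power
#' to each hemisphere of each condition. Each retained (snippet, hemisphere)
#' pair becomes one labelled sample with 4 band-power features (hemispheres
#' pooled as samples; set `hemisphere_mode = "features"` for 8 features per
#' snippet instead).
#'
#' @param recordings list of `sdr_recording` objects for one subject,
#'   covering both conditions.
#' @param epoch_len_s,reject_band,z_threshold epoch-rejection settings.
#' @param lowpass_order,half_power_hz lowpass settings.
#' @param snippet_len_s,overlap snippeting settings.
#' @param welch_window_s,welch_overlap,grid_hz Welch settings.
#' @param bands analysis bands.
#' @param hemisphere_mode `"samples"` (default) or `"features"`.
#' @param reject logical; set `FALSE` to skip epoch rejection.
#' @return object of class `sdr_feature_table`: data frame with columns
#'   `subject_id`, `condition`, `hemisphere`, `snippet_index` and one column
#'   per band, plus attribute `rejection_log`.
#' @export
build_feature_table <- function(recordings,
                                epoch_len_s = 5, reject_band = c(50, 330),
                                z_threshold = 1.5,
                                lowpass_order = 18, half_power_hz = 48,
                                snippet_len_s = 5, overlap = 0.5,
                                welch_window_s = 1, welch_overlap = 0.5,
                                grid_hz = 0.5, bands = SDR_BANDS,
                                hemisphere_mode = c("samples", "features"),
                                reject = TRUE) {
  hemisphere_mode <- match.arg(hemisphere_mode)
  conds <- vapply(recordings, function(r) r$condition, character(1))
  if (!all(SDR_CONDITIONS %in% conds))
    stopf("recordings must include both OFF and ON conditions")
  ids <- unique(vapply(recordings, function(r) r$subject_id, character(1)))
  if (length(ids) != 1) stopf("recordings mix subject ids: %s", paste(ids, collapse = ", "))

  rows <- list()
  rej_log <- list()
  for (rec in recordings) {
    fs <- rec$sampling_rate_hz
    x <- rec$samples
    if (reject) {
      mask <- reject_noisy_epochs(x, fs, epoch_len_s, reject_band, z_threshold)
      n_epoch <- round(epoch_len_s * fs)
      keep_idx <- unlist(lapply(which(mask$keep), function(i) {
        mask$epoch_starts[i]:(mask$epoch_starts[i] + n_epoch - 1L)
      }))
      x <- x[keep_idx]
      rej_log[[paste(rec$condition, rec$hemisphere, sep = "_")]] <- data.frame(
        subject_id = rec$subject_id, condition = rec$condition,
        hemisphere = rec$hemisphere, epoch_start = mask$epoch_starts,
        score = mask$rejection_scores, kept = mask$keep)
    }
    x <- lowpass_filter(x, fs, lowpass_order, half_power_hz)
    snips <- segment_snippets(x, fs, snippet_len_s, overlap)
    if (!length(snips)) next
    bp <- t(vapply(seq_along(snips), function(k) {
      sp <- welch_psd(normalize_snippet(snips[[k]]), fs,
                      window_len_s = welch_window_s,
                      overlap = welch_overlap, grid_hz = grid_hz)
      band_power(sp, bands)
    }, numeric(length(bands))))
    df <- data.frame(subject_id = rec$subject_id, condition = rec$condition,
                     hemisphere = rec$hemisphere,
                     snippet_index = seq_along(snips))
    df[paste0("bp_", vapply(bands, function(b) paste(b, collapse = "_"), character(1)))] <- bp
    rows[[length(rows) + 1L]] <- df
  }
  tab <- do.call(rbind, rows)
  for (cond in SDR_CONDITIONS) {
    if (!any(tab$condition == cond))
      stopf("no retained snippets in condition %s", cond)
  }
  if (hemisphere_mode == "features") {
    feat_cols <- setdiff(names(tab), c("subject_id", "condition", "hemisphere",
                                       "snippet_index"))
    lh <- tab[tab$hemisphere == "left", ]
    rh <- tab[tab$hemisphere == "right", ]
    m <- merge(lh, rh, by = c("subject_id", "condition", "snippet_index"),
               suffixes = c("_left", "_right"))
    m <- m[order(m$condition, m$snippet_index), ]
    m$hemisphere <- "both"
    tab <- m[c("subject_id", "condition", "hemisphere", "snippet_index",
               paste0(rep(feat_cols, each = 2), c("_left", "_right")))]
  }
  # chronological within condition: snippet index first, hemisphere second
  tab <- tab[order(tab$condition, tab$snippet_index, tab$hemisphere), ]
  rownames(tab) <- NULL
  structure(tab, class = c("sdr_feature_table", "data.frame"),
            rejection_log = if (length(rej_log)) do.call(rbind, rej_log) else NULL)
}

feature_columns <- function(table) {
  grep("^bp_", names(table), value = TRUE)
}
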