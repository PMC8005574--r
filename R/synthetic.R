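# Synthetic cohort generator. Emulates the statistical structure the
# downstream analysis assumes: per-hemisphere source-space signals made of
# four band-limited oscillatory components over a 1/f background plus white
# noise and optional high-frequency muscle bursts; MDS-UPDRS Part III item
# ratings whose medication response is coupled to the spectral effect size.

SDR_BANDS <- list(c(7, 13), c(13, 20), c(20, 30), c(35, 45))
SDR_BAND_NAMES <- c("bp_7_13", "bp_13_20", "bp_20_30", "bp_35_45")
SDR_CONDITIONS <- c("OFF", "ON")

#' Describe one synthetic subject
#'
#' Parameters of the generative model for a single subject. Band log-powers
#' are on the natural-log scale; `effect_log_power_shift` is added to the
#' baseline in the LEVODOPA-ON condition, so a shift of +1 multiplies that
#' band's variance by e in ON relative to OFF.
#'
#' @param subject_id identifier (coerced to character).
#' @param baseline_band_log_power length-4 numeric, log variance of the
#'   7-13, 13-20, 20-30 and 35-45 Hz oscillatory components. The default
#'   mimics a resting motor-cortical spectrum: prominent mu/alpha and beta,
#'   weak low gamma.
#' @param effect_log_power_shift length-4 numeric, ON-minus-OFF log-power
#'   shift per band (default all 0: no medication effect).
#' @param one_over_f_exponent spectral slope alpha of the 1/f^alpha
#'   background (default 1).
#' @param background_level standard deviation of the 1/f background
#'   component (default 1).
#' @param broadband_noise_level standard deviation of the additive white
#'   noise (default 0.5). This sets the high-frequency floor probed by the
#'   epoch-rejection rule.
#' @param artifact_burst_rate expected muscle-artifact bursts per minute
#'   (default 0: clean).
#' @param clinical_severity length-7 nonnegative numeric, latent OFF-state
#'   severity of the 7 motor factors on the 0-4 item scale.
#' @param clinical_coupling scalar mapping the Euclidean norm of
#'   `effect_log_power_shift` to the latent ON-state improvement of the
#'   coupled factors (default 0).
#' @param coupled_factors integer indices of the factors whose improvement
#'   is driven by the spectral effect (default 7, lower-limb bradykinesia).
#' @param item_noise_sd rater noise added to the latent severity of each
#'   item before rounding (default 0.5).
#' @return object of class `sdr_subject_spec`.
#' @export
subject_spec <- function(subject_id,
                         baseline_band_log_power = log(c(1.0, 0.8, 0.5, 0.1)),
                         effect_log_power_shift = c(0, 0, 0, 0),
                         one_over_f_exponent = 1,
                         background_level = 1,
                         broadband_noise_level = 0.5,
                         artifact_burst_rate = 0,
                         clinical_severity = c(1.5, 1, 1.5, 2, 2, 0.5, 1.5),
                         clinical_coupling = 0,
                         coupled_factors = 7L,
                         item_noise_sd = 0.5) {
  if (length(baseline_band_log_power) != 4 || length(effect_log_power_shift) != 4)
    stopf("band log-power vectors must have length 4")
  if (length(clinical_severity) != 7)
    stopf("'clinical_severity' must have length 7")
  if (any(clinical_severity < 0)) stopf("'clinical_severity' must be nonnegative")
  assert_scalar_num(one_over_f_exponent, "one_over_f_exponent")
  if (one_over_f_exponent < 0) stopf("'one_over_f_exponent' must be >= 0")
  assert_scalar_num(broadband_noise_level, "broadband_noise_level", positive = TRUE)
  assert_scalar_num(artifact_burst_rate, "artifact_burst_rate")
  if (artifact_burst_rate < 0) stopf("'artifact_burst_rate' must be >= 0")
  structure(list(
    subject_id = as.character(subject_id),
    baseline_band_log_power = as.numeric(baseline_band_log_power),
    effect_log_power_shift = as.numeric(effect_log_power_shift),
    one_over_f_exponent = one_over_f_exponent,
    background_level = background_level,
    broadband_noise_level = broadband_noise_level,
    artifact_burst_rate = artifact_burst_rate,
    clinical_severity = as.numeric(clinical_severity),
    clinical_coupling = clinical_coupling,
    coupled_factors = as.integer(coupled_factors),
    item_noise_sd = item_noise_sd
  ), class = "sdr_subject_spec")
}

#' Describe a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 1); ignored when `subject_specs`
#'   is given.
#' @param duration_s recording duration per condition per hemisphere in
#'   seconds (default 180, i.e. ~3 min of resting data).
#' @param sampling_rate_hz sampling rate (default 1000).
#' @param seed top-level integer seed; every signal and rating stream is
#'   derived from it.
#' @param subject_specs optional list of [subject_spec()] objects. When
#'   `NULL`, subjects are drawn from the hyperparameters below.
#' @param effect_sd per-band standard deviation of random ON-OFF log-power
#'   shifts when drawing subjects (default 0.5; ignored when
#'   `effect_range` is given).
#' @param effect_range when non-`NULL`, each drawn subject's medication
#'   effect is a uniformly random direction scaled by a magnitude drawn
#'   uniformly from `[0, effect_range]` (log units). This spreads subjects
#'   evenly across the decoder's dynamic range, which is how cohorts for
#'   brain-behaviour coupling studies are constructed here.
#' @param coupling scalar clinical coupling given to every drawn subject
#'   (default 0). When positive, the coupled factor's OFF severity is drawn
#'   high (around 3 of 4) so the medication response has headroom on the
#'   item scale.
#' @param artifact_burst_rate bursts per minute for drawn subjects
#'   (default 0).
#' @return object of class `sdr_cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20, duration_s = 180,
                        sampling_rate_hz = 1000, seed = 0,
                        subject_specs = NULL, effect_sd = 0.5,
                        effect_range = NULL,
                        coupling = 0, artifact_burst_rate = 0) {
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(sampling_rate_hz, "sampling_rate_hz", positive = TRUE)
  if (!is.null(subject_specs)) {
    ids <- vapply(subject_specs, function(s) s$subject_id, character(1))
    if (anyDuplicated(ids)) stopf("duplicate subject_id in subject_specs: %s",
                                  paste(ids[duplicated(ids)], collapse = ", "))
    n_subjects <- length(subject_specs)
  }
  if (n_subjects < 1) stopf("'n_subjects' must be >= 1")
  structure(list(
    n_subjects = as.integer(n_subjects), duration_s = duration_s,
    sampling_rate_hz = sampling_rate_hz, seed = as.integer(seed),
    subject_specs = subject_specs, effect_sd = effect_sd,
    effect_range = effect_range,
    coupling = coupling, artifact_burst_rate = artifact_burst_rate
  ), class = "sdr_cohort_spec")
}

one_over_f_noise <- function(n, fs, exponent) {
  # frequency-domain shaping of white noise; flat below 1 Hz, zero DC
  half <- n %/% 2
  f <- (1:half) * fs / n
  shape <- pmax(f, 1)^(-exponent / 2)
  pos <- complex(real = rnorm(half), imaginary = rnorm(half)) * shape
  spec <- complex(length.out = n)
  spec[2:(half + 1)] <- pos
  if (n %% 2 == 0) spec[half + 1] <- complex(real = rnorm(1) * shape[half])
  spec[n:(n - half + 2)] <- Conj(spec[2:(half)])
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

band_limited_noise <- function(n, fs, band) {
  sos <- butter_sos(4, band, fs, type = "pass")
  x <- sos_filter(sos, rnorm(n))
  x / stats::sd(x)
}

#' Generate one synthetic source-space recording
#'
#' Sum of four unit-variance band-limited Gaussian components scaled by
#' `exp(baseline + I(ON) * effect)` (variance scale), a 1/f^alpha background,
#' white noise, and Poisson-placed 0.25 s Hann-windowed 60-300 Hz bursts.
#'
#' @param spec a [subject_spec()].
#' @param condition `"OFF"` or `"ON"`.
#' @param hemisphere `"left"` or `"right"`.
#' @param duration_s duration in seconds (> 5).
#' @param fs sampling rate in Hz (>= 2 * 45 with margin; >= 100 enforced).
#' @param seed integer seed for this recording's stream.
#' @return object of class `sdr_recording`: list with `subject_id`,
#'   `condition`, `hemisphere`, `samples`, `sampling_rate_hz`.
#' @export
generate_source_signal <- function(spec, condition, hemisphere, duration_s,
                                   fs, seed) {
  condition <- match.arg(condition, SDR_CONDITIONS)
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  assert_scalar_num(duration_s, "duration_s", positive = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (duration_s <= 5) stopf("'duration_s' must exceed 5 s (one snippet)")
  if (fs < 100) stopf("'fs' must be at least 100 Hz to resolve the 35-45 Hz band")
  n <- round(duration_s * fs)
  with_seed(seed, {
    x <- numeric(n)
    logp <- spec$baseline_band_log_power +
      (condition == "ON") * spec$effect_log_power_shift
    for (b in seq_along(SDR_BANDS)) {
      x <- x + sqrt(exp(logp[b])) * band_limited_noise(n, fs, SDR_BANDS[[b]])
    }
    if (spec$background_level > 0)
      x <- x + spec$background_level * one_over_f_noise(n, fs, spec$one_over_f_exponent)
    x <- x + spec$broadband_noise_level * rnorm(n)
    if (spec$artifact_burst_rate > 0) {
      n_burst <- rpois(1, spec$artifact_burst_rate * duration_s / 60)
      if (n_burst > 0) {
        blen <- round(0.25 * fs)
        hann <- 0.5 - 0.5 * cos(2 * pi * (0:(blen - 1)) / (blen - 1))
        hi <- min(300, 0.45 * fs)
        sos_b <- butter_sos(4, c(60, hi), fs, type = "pass")
        starts <- sort(sample.int(n - blen, n_burst))
        for (s0 in starts) {
          burst <- sos_filter(sos_b, rnorm(blen))
          burst <- burst / stats::sd(burst) * 8 * spec$broadband_noise_level
          idx <- s0:(s0 + blen - 1)
          x[idx] <- x[idx] + hann * burst
        }
      }
    }
    structure(list(subject_id = spec$subject_id, condition = condition,
                   hemisphere = hemisphere, samples = x,
                   sampling_rate_hz = fs), class = "sdr_recording")
  })
}

#' Generate MDS-UPDRS Part III item ratings for one condition
#'
#' Items inherit the latent severity of their motor factor; in the ON
#' condition, factors listed in `spec$coupled_factors` have their latent
#' severity reduced by `clinical_coupling * ||effect_log_power_shift||`.
#' Rater noise is added per item, then scores are clipped to \[0, 4\] and
#' rounded to integers.
#'
#' @param spec a [subject_spec()].
#' @param condition `"OFF"` or `"ON"`.
#' @param seed integer seed for this rating's stream.
#' @return object of class `sdr_item_ratings` (see [item_ratings()]).
#' @export
generate_item_ratings <- function(spec, condition, seed) {
  condition <- match.arg(condition, SDR_CONDITIONS)
  fs <- default_factor_structure()
  sev <- spec$clinical_severity
  if (condition == "ON") {
    drop <- spec$clinical_coupling * sqrt(sum(spec$effect_log_power_shift^2))
    sev[spec$coupled_factors] <- pmax(0, sev[spec$coupled_factors] - drop)
  }
  with_seed(seed, {
    codes <- names(fs$assignment)
    lat <- sev[fs$assignment[codes]]
    noisy <- if (all(sev == 0)) rep(0, length(codes))
             else lat + rnorm(length(codes), sd = spec$item_noise_sd)
    scores <- as.integer(round(pmin(4, pmax(0, noisy))))
    names(scores) <- codes
    item_ratings(spec$subject_id, condition, scores)
  })
}

draw_subject_specs <- function(cohort) {
  with_seed(derive_seed(cohort$seed, "draw_subjects"), {
    lapply(seq_len(cohort$n_subjects), function(i) {
      effect <- if (is.null(cohort$effect_range)) {
        rnorm(4, sd = cohort$effect_sd)
      } else {
        dir <- rnorm(4)
        dir / sqrt(sum(dir^2)) * runif(1, 0, cohort$effect_range)
      }
      sev <- pmin(3.5, pmax(0.2, rnorm(7, mean = 1.5, sd = 0.7)))
      if (cohort$coupling > 0) {
        # coupled factors need OFF-state headroom for the response to show
        sev[7] <- pmin(3.5, pmax(2.5, rnorm(1, mean = 3, sd = 0.3)))
      }
      subject_spec(
        subject_id = sprintf("S%02d", i),
        effect_log_power_shift = effect,
        clinical_severity = sev,
        clinical_coupling = cohort$coupling,
        artifact_burst_rate = cohort$artifact_burst_rate
      )
    })
  })
}

#' Generate a full synthetic cohort
#'
#' All streams are derived from `cohort$seed` via [derive_seed()], so a
#' fixed spec regenerates identical signals and ratings.
#'
#' @param cohort a [cohort_spec()].
#' @return list with `recordings` (list of [generate_source_signal()]
#'   outputs, one per subject x condition x hemisphere), `ratings` (list of
#'   item ratings per subject x condition) and `ground_truth` (data frame of
#'   each subject's effect vector and coupling, for parameter-recovery
#'   tests).
#' @export
generate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "sdr_cohort_spec"))
  specs <- cohort$subject_specs %||% draw_subject_specs(cohort)
  ids <- vapply(specs, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids)) stopf("duplicate subject_id: %s",
                                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  recordings <- list()
  ratings <- list()
  for (s in specs) {
    for (cond in SDR_CONDITIONS) {
      for (hemi in c("left", "right")) {
        key <- paste(s$subject_id, cond, hemi, sep = "_")
        recordings[[key]] <- generate_source_signal(
          s, cond, hemi, cohort$duration_s, cohort$sampling_rate_hz,
          seed = derive_seed(cohort$seed, "signal", s$subject_id, cond, hemi))
      }
      ratings[[paste(s$subject_id, cond, sep = "_")]] <-
        generate_item_ratings(s, cond,
                              seed = derive_seed(cohort$seed, "ratings", s$subject_id, cond))
    }
  }
  gt <- data.frame(
    subject_id = ids,
    t(vapply(specs, function(s) s$effect_log_power_shift, numeric(4))),
    coupling = vapply(specs, function(s) s$clinical_coupling, numeric(1))
  )
  names(gt)[2:5] <- paste0("effect_", SDR_BAND_NAMES)
  list(recordings = recordings, ratings = ratings, ground_truth = gt,
       subject_specs = specs, spec = cohort)
}

#' A contaminated-subject preset
#'
#' Same defaults as [subject_spec()] but with muscle-artifact bursts at 6
#' per minute, for exercising the epoch-rejection rule.
#' @param subject_id identifier.
#' @param artifact_burst_rate bursts per minute (default 6).
#' @param ... further arguments passed to [subject_spec()].
#' @export
contaminated_subject_spec <- function(subject_id, artifact_burst_rate = 6, ...) {
  subject_spec(subject_id, artifact_burst_rate = artifact_burst_rate, ...)
}
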