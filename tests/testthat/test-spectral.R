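test_that("epoch rejection flags exactly the contaminated epoch", {
  fs <- 1000
  set.seed(13)
  x <- rnorm(30 * fs)                     # six 5 s epochs
  t_burst <- (10 * fs + 1):(11 * fs)      # inside epoch 3
  x[t_burst] <- x[t_burst] + 8 * sin(2 * pi * 200 * seq_along(t_burst) / fs)
  mask <- reject_noisy_epochs(x, fs)
  expect_length(mask$keep, 6)
  expect_equal(which(!mask$keep), 3)
  # oracle: direct per-epoch band power ordering
  scores <- vapply(0:5, function(e) {
    periodogram_band_power(x[(e * 5 * fs + 1):((e + 1) * 5 * fs)], fs, c(50, 330))
  }, numeric(1))
  expect_equal(which.max(scores), 3)
  expect_gt(scores[3] / max(scores[-3]), 5)
})

test_that("epoch rejection degenerate cases follow the rule", {
  fs <- 200
  one <- rnorm(5 * fs)
  expect_warning(mask <- reject_noisy_epochs(one, fs), "Nyquist")
  expect_true(all(mask$keep))             # single epoch: sd = 0, kept
  # identical epochs: sd = 0, threshold equals the mean, none rejected
  ep <- rnorm(5 * 1000)
  mask2 <- reject_noisy_epochs(rep(ep, 4), 1000)
  expect_true(all(mask2$keep))
  expect_error(reject_noisy_epochs(rnorm(100), 1000), "shorter")
})

test_that("lowpass filter passes DC and refuses invalid rates", {
  y <- lowpass_filter(rep(1, 3000), 1000)
  expect_equal(y[2000:3000], rep(1, 1001), tolerance = 1e-6)
  expect_error(lowpass_filter(rnorm(100), 96), "exceed")
})

test_that("snippet segmentation enumerates 50%-overlap start times", {
  fs <- 1000
  expect_length(segment_snippets(rnorm(5 * fs), fs), 1)
  # 180 s: floor((180 - 5) / 2.5) + 1 = 71
  expect_length(segment_snippets(rnorm(180 * fs), fs), 71)
  expect_warning(out <- segment_snippets(rnorm(4 * fs), fs), "shorter")
  expect_length(out, 0)
  snips <- segment_snippets(seq_len(10 * fs), fs)
  expect_equal(snips[[2]][1], 2.5 * fs + 1)   # hop is 2.5 s
  expect_true(all(lengths(snips) == 5 * fs))
})

test_that("snippet normalisation is an exact affine projection", {
  set.seed(2)
  x <- rnorm(500, mean = 3, sd = 2)
  z <- normalize_snippet(x)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(stats::var(z) - 1), 1e-8)
  expect_equal(normalize_snippet(5 * x - 7), z, tolerance = 1e-12)
  expect_equal(normalize_snippet(z), z, tolerance = 1e-10)
  expect_error(normalize_snippet(rep(1, 100)), "constant")
})

test_that("vertex spectrum averaging is an element-wise mean", {
  f <- seq(0, 50, by = 0.5)
  a <- sdrdecode:::new_spectrum(f, rep(0, length(f)))
  b <- sdrdecode:::new_spectrum(f, rep(2, length(f)))
  avg <- average_vertex_spectra(list(a, b))
  expect_equal(avg$power, rep(1, length(f)))
  expect_equal(average_vertex_spectra(list(b))$power, b$power)
  set.seed(4)
  sps <- lapply(1:5, function(i) sdrdecode:::new_spectrum(f, runif(length(f))))
  brute <- colMeans(do.call(rbind, lapply(sps, `[[`, "power")))
  expect_equal(average_vertex_spectra(sps)$power, brute, tolerance = 1e-12)
  g <- sdrdecode:::new_spectrum(f + 0.1, rep(1, length(f)))
  expect_error(average_vertex_spectra(list(a, g)), "grids")
})

test_that("band power integrates half-open bands by the mean rule", {
  f <- seq(0, 50, by = 0.5)
  flat <- sdrdecode:::new_spectrum(f, rep(1, length(f)))
  expect_equal(band_power(flat), rep(1, 4))
  ind <- sdrdecode:::new_spectrum(f, as.numeric(f >= 20 & f < 30))
  expect_equal(band_power(ind), c(0, 0, 1, 0))
  # 13 Hz belongs to the 13-20 band only
  spike <- sdrdecode:::new_spectrum(f, as.numeric(f == 13))
  bp <- band_power(spike)
  expect_equal(bp[1], 0)
  expect_gt(bp[2], 0)
  set.seed(6)
  rnd <- sdrdecode:::new_spectrum(f, runif(length(f)))
  brute <- vapply(list(c(7, 13), c(13, 20), c(20, 30), c(35, 45)), function(b) {
    mean(rnd$power[f >= b[1] & f < b[2]])
  }, numeric(1))
  expect_equal(band_power(rnd), brute, tolerance = 1e-12)
  expect_error(band_power(flat, bands = list(c(40, 80))), "outside")
})

test_that("the feature table composes the stages with the expected shape", {
  s <- subject_spec("ft")
  recs <- make_subject_recordings(s, duration_s = 20, seed = 31)
  tab <- build_feature_table(recs)
  # 20 s -> 4 epochs kept (clean) -> 7 snippets per hemisphere per condition
  expect_equal(nrow(tab), 7 * 2 * 2)
  expect_setequal(unique(tab$condition), c("OFF", "ON"))
  expect_true(all(is.finite(as.matrix(tab[grep("^bp_", names(tab))]))))
  expect_true(all(as.matrix(tab[grep("^bp_", names(tab))]) >= 0))
  # determinism
  expect_equal(tab, build_feature_table(recs))
  # scale invariance: snippets are z-normalized before spectra (rejection
  # scores scale with the signal, so attributes are excluded on purpose)
  recs_scaled <- lapply(recs, function(r) { r$samples <- 5 * r$samples; r })
  expect_equal(as.data.frame(build_feature_table(recs_scaled)),
               as.data.frame(tab), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("contaminated recordings lose epochs and hence snippets", {
  # a low burst rate leaves most epochs clean, so burst epochs stand out
  # against the adaptive 1.5 sd threshold
  sd_ <- contaminated_subject_spec("dirty", artifact_burst_rate = 2)
  recs <- make_subject_recordings(sd_, duration_s = 60, seed = 77)
  tab_dirty <- build_feature_table(recs)
  s <- subject_spec("clean")
  tab_clean <- build_feature_table(make_subject_recordings(s, duration_s = 60,
                                                           seed = 77))
  log_dirty <- attr(tab_dirty, "rejection_log")
  log_clean <- attr(tab_clean, "rejection_log")
  expect_gt(sum(!log_dirty$kept), sum(!log_clean$kept))
  expect_lt(nrow(tab_dirty), nrow(tab_clean))
})

test_that("adding 20-30 Hz power raises band 3 and leaks < 10% into others", {
  # leakage is a property of the band filters and Welch estimator, so it is
  # assessed on raw (un-normalised) spectra; z-normalisation afterwards
  # rescales all bands by total power by design
  s <- subject_spec("m0")
  s_hi <- subject_spec("m1", baseline_band_log_power = log(c(1.0, 0.8, 1.5, 0.1)))
  bp <- function(spec, seed) {
    r <- generate_source_signal(spec, "OFF", "left", 60, 1000, seed)
    band_power(welch_psd(r$samples, 1000))
  }
  m0 <- (bp(s, 55) + bp(s, 56)) / 2
  m1 <- (bp(s_hi, 55) + bp(s_hi, 56)) / 2
  expect_gt(m1[3], m0[3])
  expect_lt(max(abs(m1[-3] / m0[-3] - 1)), 0.10)
  # after per-snippet normalisation the contrast still reaches feature 3
  t0 <- build_feature_table(make_subject_recordings(s, duration_s = 30, seed = 55))
  t1 <- build_feature_table(make_subject_recordings(s_hi, duration_s = 30, seed = 55))
  expect_gt(mean(t1$bp_20_30), mean(t0$bp_20_30))
})

test_that("hemisphere feature mode yields 8 features per snippet", {
  s <- subject_spec("hf")
  recs <- make_subject_recordings(s, duration_s = 20, seed = 91)
  tab <- build_feature_table(recs, hemisphere_mode = "features")
  expect_equal(nrow(tab), 7 * 2)
  expect_length(grep("^bp_", names(tab)), 8)
})
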