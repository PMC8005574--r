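# Minimal IIR/spectral toolbox: Butterworth design in zpk form with bilinear
# transform, second-order-section filtering, Welch and raw periodogram
# estimators. Only even filter orders are needed by the pipeline (18th-order
# lowpass, 4th-order band-pass), which keeps the section pairing trivial:
# every digital pole arrives as a conjugate pair.

#' Design a Butterworth filter as second-order sections
#'
#' Lowpass (`type = "low"`) or band-pass (`type = "pass"`) Butterworth design
#' via the analog prototype, frequency prewarping and the bilinear transform.
#' The filter is returned as a matrix of second-order sections (columns
#' `b0,b1,b2,a0,a1,a2`), the numerically robust form for high orders: the
#' 18th-order lowpass used on 1 kHz signals is badly conditioned as a single
#' polynomial but exact in cascade form.
#'
#' @param order filter order (even). For `"pass"` this is the prototype
#'   order; the digital filter has `2 * order` poles.
#' @param cutoff_hz half-power frequency in Hz (scalar for `"low"`, length-2
#'   ascending for `"pass"`).
#' @param fs sampling rate in Hz.
#' @param type `"low"` or `"pass"`.
#' @return matrix with one row per biquad section and attributes `fs`.
#' @export
butter_sos <- function(order, cutoff_hz, fs, type = c("low", "pass")) {
  type <- match.arg(type)
  assert_scalar_num(order, "order", positive = TRUE)
  assert_scalar_num(fs, "fs", positive = TRUE)
  if (order %% 2 != 0) stopf("only even Butterworth orders are supported (got %d)", order)
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= fs / 2))
    stopf("cutoff frequencies must lie strictly inside (0, fs/2)")

  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LHP poles

  warp <- function(f) 2 * fs * tan(pi * f / fs)
  if (type == "low") {
    wc <- warp(cutoff_hz[1])
    poles_s <- wc * proto
    f_ref <- 0
  } else {
    if (length(cutoff_hz) != 2L) stopf("band-pass design needs two cutoff frequencies")
    w1 <- warp(cutoff_hz[1]); w2 <- warp(cutoff_hz[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    # lowpass-to-bandpass: each prototype pole p maps to the roots of
    # s^2 - (bw p) s + w0^2 = 0
    poles_s <- c(
      (bw * proto + sqrt((bw * proto)^2 - 4 * w0^2)) / 2,
      (bw * proto - sqrt((bw * proto)^2 - 4 * w0^2)) / 2
    )
    f_ref <- (fs / pi) * atan(w0 / (2 * fs))  # digital centre frequency
  }

  poles_z <- (1 + poles_s / (2 * fs)) / (1 - poles_s / (2 * fs))
  if (any(abs(poles_z) >= 1)) stopf("unstable design: pole outside the unit circle")

  up <- poles_z[Im(poles_z) > 0]
  # sort sections from least to most resonant for cascade robustness
  up <- up[order(abs(up))]
  n_sec <- length(up)
  if (2L * n_sec != length(poles_z)) stopf("internal error: poles did not pair")

  b_sec <- if (type == "low") c(1, 2, 1) else c(1, 0, -1)
  sos <- t(vapply(up, function(q) {
    c(b_sec, 1, -2 * Re(q), abs(q)^2)
  }, numeric(6)))
  colnames(sos) <- c("b0", "b1", "b2", "a0", "a1", "a2")

  g <- abs(sos_freq_response(sos, f_ref, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  attr(sos, "fs") <- fs
  sos
}

#' Frequency response of a second-order-section cascade
#'
#' @param sos section matrix from [butter_sos()].
#' @param f frequencies in Hz.
#' @param fs sampling rate in Hz.
#' @return complex response at each frequency.
#' @export
sos_freq_response <- function(sos, f, fs) {
  z1 <- exp(-1i * 2 * pi * f / fs)
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    num <- sos[[s, 1]] + sos[[s, 2]] * z1 + sos[[s, 3]] * z1^2
    den <- sos[[s, 4]] + sos[[s, 5]] * z1 + sos[[s, 6]] * z1^2
    h <- h * num / den
  }
  unname(h)
}

#' Filter a signal through second-order sections (single pass, zero state)
#'
#' Causal direct-form filtering; each biquad runs its moving-average part as
#' a convolution and its recursive part through `stats::filter`, which is
#' implemented in C.
#'
#' @param sos section matrix from [butter_sos()].
#' @param x numeric signal.
#' @return filtered signal, same length as `x`.
#' @export
sos_filter <- function(sos, x) {
  y <- as.numeric(x)
  n <- length(y)
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3] / sos[s, 4]
    a <- sos[s, 5:6] / sos[s, 4]
    xp <- c(0, 0, y)
    u <- b[1] * xp[3:(n + 2)] + b[2] * xp[2:(n + 1)] + b[3] * xp[1:n]
    y <- as.numeric(stats::filter(u, -a, method = "recursive"))
  }
  y
}

hamming_window <- function(n) {
  if (n == 1) return(1)
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Welch power spectral density on a fixed frequency grid
#'
#' Averaged modified periodograms of Hamming-windowed segments with 50%
#' overlap. Windows are zero-padded so the output grid spacing equals
#' `grid_hz` (1 s windows at `grid_hz = 0.5` are padded to a 2 s transform).
#' One-sided density normalisation: for a stationary signal the integral of
#' the PSD over frequency approximates the signal variance.
#'
#' @param x numeric signal (one snippet).
#' @param fs sampling rate in Hz.
#' @param window_len_s segment length in seconds (default 1).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param grid_hz frequency resolution of the output grid (default 0.5).
#' @return object of class `sdr_spectrum`: list with `frequencies_hz` and
#'   `power`.
#' @export
welch_psd <- function(x, fs, window_len_s = 1, overlap = 0.5, grid_hz = 0.5) {
  assert_scalar_num(fs, "fs", positive = TRUE)
  nwin <- round(window_len_s * fs)
  if (length(x) < nwin)
    stopf("snippet of %d samples is shorter than one %g s window", length(x), window_len_s)
  step <- max(1L, round(nwin * (1 - overlap)))
  nfft <- max(nwin, round(fs / grid_hz))
  w <- hamming_window(nwin)
  u <- sum(w^2)  # window energy for density normalisation
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  acc <- numeric(nfft %/% 2 + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nwin - 1L)] * w
    X <- stats::fft(c(seg, numeric(nfft - nwin)))
    p <- Mod(X[1:(nfft %/% 2 + 1)])^2 / (fs * u)
    acc <- acc + p
  }
  pxx <- acc / length(starts)
  # one-sided: double everything except DC (and Nyquist when nfft is even)
  dbl <- 2:(length(pxx) - if (nfft %% 2 == 0) 1 else 0)
  pxx[dbl] <- 2 * pxx[dbl]
  new_spectrum((0:(nfft %/% 2)) * fs / nfft, pxx)
}

new_spectrum <- function(frequencies_hz, power) {
  structure(list(frequencies_hz = frequencies_hz, power = power),
            class = "sdr_spectrum")
}

#' @export
print.sdr_spectrum <- function(x, ...) {
  cat(sprintf("<sdr_spectrum> %d bins, %g-%g Hz, spacing %g Hz\n",
              length(x$frequencies_hz), min(x$frequencies_hz),
              max(x$frequencies_hz), x$frequencies_hz[2] - x$frequencies_hz[1]))
  invisible(x)
}

#' Mean raw-periodogram power of a signal in a frequency band
#'
#' Single (boxcar) periodogram with density normalisation; used by the
#' high-frequency epoch-rejection rule where spectral resolution is
#' unimportant but speed matters.
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param band length-2 band in Hz; the upper edge is clipped to Nyquist.
#' @return mean PSD over bins with `band[1] <= f <= band[2]`.
#' @export
periodogram_band_power <- function(x, fs, band) {
  n <- length(x)
  X <- stats::fft(x)
  half <- n %/% 2 + 1
  p <- Mod(X[1:half])^2 / (fs * n)
  dbl <- 2:(half - if (n %% 2 == 0) 1 else 0)
  p[dbl] <- 2 * p[dbl]
  f <- (0:(half - 1)) * fs / n
  hi <- min(band[2], fs / 2)
  sel <- f >= band[1] & f <= hi
  if (!any(sel)) stopf("band [%g, %g] Hz contains no periodogram bins", band[1], band[2])
  mean(p[sel])
}
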