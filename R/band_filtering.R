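#' Convert a cutoff frequency to a normalized frequency
#'
#' Digital filter design expresses band edges as a fraction of the Nyquist
#' frequency: `Wn = fcutoff / (fs / 2)`, so the Nyquist frequency maps to 1.
#'
#' @param fcutoff Cutoff frequency in Hz, `0 < fcutoff <= fs/2`.
#' @param fs Sampling rate in Hz.
#' @return Dimensionless fraction in (0, 1].
#' @export
#' @examples
#' normalized_frequency(50, 500)  # 0.2
normalized_frequency <- function(fcutoff, fs) {
  if (any(fs <= 0)) abort("`fs` must be positive.", class = "eegauth_domain_error")
  if (any(fcutoff <= 0) || any(fcutoff > fs / 2)) {
    abort("`fcutoff` must lie in (0, fs/2].", class = "eegauth_domain_error")
  }
  fcutoff / (fs / 2)
}

#' Band-pass filter specification
#'
#' @param f_low,f_high Pass-band edges in Hz, `0 < f_low < f_high <= fs/2`.
#' @param order Butterworth order per edge (the band-pass filter has
#'   `2 * order` poles).
#' @param fs Sampling rate in Hz.
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(f_low, f_high, order, fs) {
  if (length(order) != 1L || order < 1 || order != round(order)) {
    abort("`order` must be a positive integer.", class = "eegauth_domain_error")
  }
  if (fs <= 0 || f_low <= 0 || f_low >= f_high || f_high > fs / 2) {
    abort("Band edges must satisfy 0 < f_low < f_high <= fs/2.",
          class = "eegauth_domain_error")
  }
  structure(
    list(f_low = f_low, f_high = f_high, order = as.integer(order), fs = fs),
    class = "filter_spec"
  )
}

#' Canonical frequency-band table
#'
#' The six analysis bands: the overall pass-band and the five EEG sub-bands.
#' All bands use a 4th-order Butterworth design except delta, whose 0.2 Hz
#' high-pass edge sits below the stable range of higher-order IIR designs and
#' is therefore extracted with a 2nd-order filter.
#'
#' @return A tibble with columns `band`, `f_low`, `f_high`, `order`.
#' @export
#' @examples
#' band_definitions()
band_definitions <- function() {
  tibble::tibble(
    band = BAND_NAMES,
    f_low = c(0.2, 0.2, 4, 8, 12, 26),
    f_high = c(50, 4, 8, 12, 26, 50),
    order = c(4L, 2L, 4L, 4L, 4L, 4L)
  )
}

# --- Butterworth band-pass design in second-order sections ------------------
#
# Transfer-function coefficients of a band-pass Butterworth with a 0.2 Hz
# edge at fs = 500 Hz are numerically ill-conditioned (poles crowd z = 1), so
# the filter is designed in zero-pole-gain form and factored into biquads:
# analog low-pass prototype poles -> low-pass-to-band-pass transform with
# prewarped edges -> bilinear transform. Each biquad carries one zero at
# z = +1 and one at z = -1 (the DC and Nyquist zeros of a band-pass), with
# the overall gain spread evenly across sections.

butter_bandpass_sos <- function(spec) {
  n <- spec$order
  fs <- spec$fs
  # prewarped analog edge frequencies (rad/s), bilinear convention s = 2fs(z-1)/(z+1)
  w1 <- 2 * fs * tan(pi * spec$f_low / fs)
  w2 <- 2 * fs * tan(pi * spec$f_high / fs)
  bw <- w2 - w1
  w0 <- sqrt(w1 * w2)

  # analog low-pass prototype poles on the unit circle, left half-plane
  k <- seq_len(n)
  p_lp <- exp(1i * pi * (2 * k + n - 1) / (2 * n))

  # low-pass -> band-pass: each prototype pole splits into two
  b <- p_lp * bw / 2
  p_bp <- c(b + sqrt(b^2 - w0^2), b - sqrt(b^2 - w0^2))
  gain_a <- bw^n  # n analog zeros at s = 0

  # bilinear transform to the z-plane
  p_z <- (2 * fs + p_bp) / (2 * fs - p_bp)
  gain_d <- gain_a * Re((2 * fs)^n / prod(2 * fs - p_bp))

  # pair poles into biquad denominators (conjugate or real pairs),
  # innermost poles first
  remaining <- p_z
  dens <- matrix(0, nrow = n, ncol = 2L)
  for (i in seq_len(n)) {
    j <- which.min(Mod(remaining))
    p <- remaining[j]
    remaining <- remaining[-j]
    j2 <- which.min(Mod(remaining - Conj(p)))
    q <- remaining[j2]
    remaining <- remaining[-j2]
    dens[i, ] <- c(-Re(p + q), Re(p * q))
  }
  sec_gain <- abs(gain_d)^(1 / n)
  sos <- cbind(
    b0 = rep(sec_gain, n), b1 = 0, b2 = -sec_gain,  # zeros at z = +1 and -1
    a1 = dens[, 1], a2 = dens[, 2]
  )
  if (gain_d < 0) sos[1L, 1:3] <- -sos[1L, 1:3]
  sos
}

# one biquad pass started in steady state for a constant input `x_ss`:
# exactly zero transient for constant signals, which (with odd-reflection
# padding) suppresses the slow edge transients of near-unit-circle poles
biquad_filter <- function(x, b0, b1, b2, a1, a2, x_ss) {
  n <- length(x)
  h1 <- (b0 + b1 + b2) / (1 + a1 + a2)   # DC gain
  u <- b0 * x +
    b1 * c(x_ss, x[-n]) +
    b2 * c(x_ss, x_ss, x[-c(n - 1L, n)])
  y_ss <- h1 * x_ss
  as.numeric(stats::filter(u, c(-a1, -a2), method = "recursive",
                           init = c(y_ss, y_ss)))
}

sos_filter <- function(x, sos) {
  x_ss <- x[1]
  for (i in seq_len(nrow(sos))) {
    b0 <- sos[i, 1]; b1 <- sos[i, 2]; b2 <- sos[i, 3]
    a1 <- sos[i, 4]; a2 <- sos[i, 5]
    x <- biquad_filter(x, b0, b1, b2, a1, a2, x_ss)
    x_ss <- x_ss * (b0 + b1 + b2) / (1 + a1 + a2)
  }
  x
}

# forward-backward filtering with odd-reflection padding: zero phase, squared
# magnitude response. The pad covers at least three time constants of the
# slowest pole (clamped to the signal length), so slow high-pass-edge
# transients decay inside the pad rather than in the retained samples.
filtfilt_sos <- function(x, sos) {
  n <- length(x)
  min_pad <- 3L * (2L * nrow(sos) * 2L + 1L)
  if (n <= min_pad) {
    abort(
      sprintf("Signal too short to filter: need more than %d samples, got %d.",
              min_pad, n),
      class = "eegauth_length_error"
    )
  }
  r_max <- sqrt(min(max(sos[, 5]), 1 - 1e-12))
  tau <- -1 / log(r_max)
  padlen <- min(max(min_pad, as.integer(ceiling(3 * tau))), n - 1L)
  pre <- 2 * x[1] - x[(padlen + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - padlen)]
  ext <- c(pre, x, post)
  ext <- sos_filter(ext, sos)
  ext <- rev(sos_filter(rev(ext), sos))
  ext[(padlen + 1L):(padlen + n)]
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel of a recording. The filter is designed as second-order sections
#' for numerical stability at low normalized edge frequencies; the two-pass
#' application squares the magnitude response and cancels phase distortion.
#' Output length equals input length.
#'
#' @param rec An [eeg_recording()].
#' @param spec A [filter_spec()]; its `fs` must match the recording's.
#' @return A filtered `eeg_recording` of identical shape and labels, with the
#'   applied spec attached as attribute `"filter_spec"`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), 2, 1000), fs = 500,
#'                      channel_labels = c("Fp1", "Fp2"))
#' flt <- bandpass_filter(rec, filter_spec(0.2, 50, 4, 500))
bandpass_filter <- function(rec, spec) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(spec, "filter_spec"))
  if (!isTRUE(all.equal(spec$fs, rec$fs))) {
    abort("Filter and recording sampling rates differ.", class = "eegauth_domain_error")
  }
  sos <- butter_bandpass_sos(spec)
  filtered <- t(apply(rec$data, 1L, filtfilt_sos, sos = sos))
  out <- eeg_recording(filtered, fs = rec$fs,
                       channel_labels = rec$channel_labels,
                       subject_id = rec$subject_id)
  attr(out, "filter_spec") <- spec
  out
}

#' Extract the five EEG sub-bands from an overall-band recording
#'
#' Splits a recording (already restricted to the 0.2-50 Hz overall band) into
#' delta (0.2-4 Hz), theta (4-8 Hz), alpha (8-12 Hz), beta (12-26 Hz) and
#' gamma (26-50 Hz) by zero-phase Butterworth filtering, and passes the
#' overall band through unchanged. Adjacent bands share their common edge.
#'
#' @param rec An [eeg_recording()], band-passed to the overall band.
#' @param bands Which of the six bands to return (default all).
#' @return Named list of `eeg_recording`s (`overall` plus the sub-bands),
#'   each with the same shape and labels as the input and the applied band
#'   row attached as attribute `"band_definition"`.
#' @export
extract_bands <- function(rec, bands = BAND_NAMES) {
  stopifnot(inherits(rec, "eeg_recording"))
  bands <- match.arg(bands, BAND_NAMES, several.ok = TRUE)
  defs <- band_definitions()
  defs <- defs[defs$band %in% bands, ]
  out <- lapply(seq_len(nrow(defs)), function(i) {
    d <- defs[i, ]
    if (d$band == "overall") {
      r <- rec
    } else {
      r <- bandpass_filter(rec, filter_spec(d$f_low, d$f_high, d$order, rec$fs))
    }
    attr(r, "band_definition") <- as.list(d)
    r
  })
  names(out) <- defs$band
  out
}
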