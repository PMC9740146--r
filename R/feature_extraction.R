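#' Windowing specification
#'
#' Overlapping rectangular windows: 0.5 s windows advanced in 0.25 s steps by
#' default, so each window shares half its samples with its neighbours.
#' Sample counts are rounded half away from zero.
#'
#' @param length Window length in seconds (default 0.5).
#' @param step Hop between window starts in seconds (default 0.25);
#'   `0 < step <= length`.
#' @return A `window_spec` object.
#' @export
window_spec <- function(length = 0.5, step = 0.25) {
  if (step <= 0 || step > length) {
    abort("Window spec must satisfy 0 < step <= length.", class = "eegauth_domain_error")
  }
  structure(list(length = length, step = step), class = "window_spec")
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

window_samples <- function(wspec, fs) {
  list(
    length = as.integer(round_half_away(wspec$length * fs)),
    step = as.integer(round_half_away(wspec$step * fs))
  )
}

# start indices of complete windows in a signal of n samples
window_starts <- function(n, L, S) {
  if (n < L) return(integer(0))
  seq.int(1L, n - L + 1L, by = S)
}

#' Segment a recording into overlapping windows
#'
#' Windows start at the first sample and advance by the step size; a trailing
#' partial window is dropped. The window count is
#' `floor((N - L) / S) + 1` for `N` samples, window length `L` and step `S`
#' (in samples).
#'
#' @param rec An [eeg_recording()].
#' @param wspec A [window_spec()].
#' @return List of channels x window-length matrices, one per window. A
#'   recording shorter than one window yields an empty list with a warning.
#' @export
window_signal <- function(rec, wspec = window_spec()) {
  stopifnot(inherits(rec, "eeg_recording"))
  ws <- window_samples(wspec, rec$fs)
  starts <- window_starts(ncol(rec$data), ws$length, ws$step)
  if (length(starts) == 0L) {
    warn("Recording is shorter than one window; returning no windows.")
    return(list())
  }
  lapply(starts, function(s) rec$data[, s:(s + ws$length - 1L), drop = FALSE])
}

#' Compute the per-window feature set
#'
#' The 11 named window descriptors, in canonical order: mean; population
#' standard deviation; mean absolute value; root mean square; skewness
#' (biased moment estimator `m3 / m2^1.5`); kurtosis (non-excess,
#' `m4 / m2^2`, 3 for a Gaussian); Hjorth activity (population variance),
#' mobility (`sqrt(var(dx) / var(x))`) and complexity
#' (`mobility(dx) / mobility(x)`, first differences); Shannon entropy of a
#' fixed-bin amplitude histogram (bits); and spectral entropy of the
#' normalized periodogram, scaled to `[0, 1]` by `log2` of the number of
#' spectral bins. Zero-variance windows take 0 for the moment ratios and
#' Hjorth ratios; a constant signal has zero entropy.
#'
#' @param x Numeric sample vector (one window of one channel), length >= 3.
#' @param fs Sampling rate in Hz (kept for interface symmetry; the features
#'   are ratio-based and do not rescale by `fs`).
#' @param n_bins Histogram bin count for Shannon entropy (default 16).
#' @return Named numeric vector of length 11.
#' @export
#' @examples
#' compute_features(sin(2 * pi * 10 * (0:249) / 500), fs = 500)
compute_features <- function(x, fs, n_bins = 16L) {
  if (length(x) < 3L) abort("Window must hold at least 3 samples.", class = "eegauth_validation_error")
  if (!all(is.finite(x))) abort("Window contains non-finite samples.", class = "eegauth_validation_error")
  s <- max(abs(x))
  if (s > 1e100) {
    # rescale so squared moments cannot overflow; amplitude features scale back
    f <- compute_features(x / s, fs, n_bins)
    amp <- c("mean", "sd", "mav", "rms")
    f[amp] <- f[amp] * s
    f["activity"] <- (f["activity"] * s) * s  # two steps: 0 * Inf guard
    return(f)
  }
  m <- mean(x)
  xc <- x - m
  m2 <- mean(xc^2)
  out <- c(
    mean = m,
    sd = sqrt(m2),
    mav = mean(abs(x)),
    rms = sqrt(mean(x^2)),
    skewness = if (m2 > 0) mean(xc^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(xc^4) / m2^2 else 0,
    activity = m2,
    hjorth_mobility_complexity(x, m2),
    shannon_entropy = shannon_entropy(x, n_bins),
    spectral_entropy = spectral_entropy(x)
  )
  out
}

# mobility and complexity from population variances of the signal and its
# first and second differences; 0 whenever a denominator variance vanishes
hjorth_mobility_complexity <- function(x, v0 = NULL) {
  pvar <- function(z) mean((z - mean(z))^2)
  if (is.null(v0)) v0 <- pvar(x)
  d1 <- diff(x)
  d2 <- diff(d1)
  v1 <- pvar(d1)
  v2 <- if (length(d2)) pvar(d2) else 0
  mob <- if (v0 > 0) sqrt(v1 / v0) else 0
  mob_d <- if (v1 > 0) sqrt(v2 / v1) else 0
  comp <- if (mob > 0) mob_d / mob else 0
  c(mobility = mob, complexity = comp)
}

# Shannon entropy (bits) of a fixed-width amplitude histogram over the
# window's min-max range; 0 for a constant window
shannon_entropy <- function(x, n_bins = 16L) {
  lo <- min(x)
  hi <- max(x)
  if (hi == lo) return(0)
  idx <- pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  p <- tabulate(idx, nbins = n_bins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# normalized spectral entropy over the one-sided periodogram (DC excluded)
spectral_entropy <- function(x) {
  n <- length(x)
  P <- Mod(fft(x))^2
  P <- P[2:(floor(n / 2) + 1L)]
  tot <- sum(P)
  if (tot <= 0) return(0)
  p <- P / tot
  p <- p[p > 0]
  -sum(p * log2(p)) / log2(length(P))
}

# vectorized feature computation over a window matrix W (window-length x
# n-windows); must agree with compute_features() column by column
features_matrix <- function(W, n_bins = 16L) {
  L <- nrow(W)
  nw <- ncol(W)
  m <- colMeans(W)
  xc <- sweep(W, 2L, m)
  m2 <- colMeans(xc^2)
  m3 <- colMeans(xc^3)
  m4 <- colMeans(xc^4)
  pos <- m2 > 0
  pvar_cols <- function(M) colMeans(M^2) - colMeans(M)^2
  D1 <- diff(W)
  D2 <- diff(D1)
  v1 <- pvar_cols(D1)
  v2 <- pvar_cols(D2)
  mob <- ifelse(pos, sqrt(pmax(v1, 0) / pmax(m2, .Machine$double.xmin)), 0)
  mob_d <- ifelse(v1 > 0, sqrt(pmax(v2, 0) / pmax(v1, .Machine$double.xmin)), 0)
  comp <- ifelse(mob > 0, mob_d / pmax(mob, .Machine$double.xmin), 0)

  sh <- vapply(seq_len(nw), function(j) shannon_entropy(W[, j], n_bins), 0)
  FP <- Mod(mvfft(W))^2
  FP <- FP[2:(floor(L / 2) + 1L), , drop = FALSE]
  tot <- colSums(FP)
  se <- vapply(seq_len(nw), function(j) {
    if (tot[j] <= 0) return(0)
    p <- FP[, j] / tot[j]
    p <- p[p > 0]
    -sum(p * log2(p)) / log2(nrow(FP))
  }, 0)

  out <- cbind(
    mean = m,
    sd = sqrt(m2),
    mav = colMeans(abs(W)),
    rms = sqrt(colMeans(W^2)),
    skewness = ifelse(pos, m3 / pmax(m2, .Machine$double.xmin)^1.5, 0),
    kurtosis = ifelse(pos, m4 / pmax(m2, .Machine$double.xmin)^2, 0),
    activity = m2,
    mobility = mob,
    complexity = comp,
    shannon_entropy = sh,
    spectral_entropy = se
  )
  out
}

#' Canonical feature names
#' @return Character vector of the 11 feature names in column order.
#' @export
feature_names <- function() FEATURE_NAMES

#' Build a windows-by-(channel x feature) feature table
#'
#' Segments one band's recording into overlapping windows and computes every
#' channel's feature set per window. Columns are channel-major — all features
#' of the first channel, then the second — and named
#' `<channel label>_<feature>`.
#'
#' @param band_rec An [eeg_recording()] (typically one entry of
#'   [extract_bands()]).
#' @param wspec A [window_spec()].
#' @param band Band name stored with the table (default from the recording's
#'   `band_definition` attribute when present).
#' @param n_bins Histogram bin count for Shannon entropy.
#' @return A tibble of class `feature_tbl` with columns `subject`, `window`,
#'   then `n_channels * 11` feature columns; attributes `channel_labels`,
#'   `feature_names` and `band` record column provenance.
#' @export
build_feature_table <- function(band_rec, wspec = window_spec(), band = NULL,
                                n_bins = 16L) {
  stopifnot(inherits(band_rec, "eeg_recording"))
  if (is.null(band)) {
    bd <- attr(band_rec, "band_definition")
    band <- if (is.null(bd)) NA_character_ else bd$band
  }
  ws <- window_samples(wspec, band_rec$fs)
  starts <- window_starts(ncol(band_rec$data), ws$length, ws$step)
  if (length(starts) == 0L) {
    warn("Recording is shorter than one window; returning an empty table.")
    starts <- integer(0)
  }
  idx <- outer(seq_len(ws$length) - 1L, starts, `+`)  # L x n_windows indices
  blocks <- lapply(seq_along(band_rec$channel_labels), function(ch) {
    Fm <- features_matrix(matrix(band_rec$data[ch, idx], nrow = ws$length),
                          n_bins = n_bins)
    colnames(Fm) <- paste(band_rec$channel_labels[ch], FEATURE_NAMES, sep = "_")
    Fm
  })
  mat <- do.call(cbind, blocks)
  out <- tibble::as_tibble(as.data.frame(mat))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject = rep(band_rec$subject_id, length(starts)),
      window = seq_along(starts)
    ),
    out
  )
  new_feature_tbl(out, channel_labels = band_rec$channel_labels, band = band)
}

new_feature_tbl <- function(tbl, channel_labels, band) {
  structure(
    tbl,
    channel_labels = channel_labels,
    feature_names = FEATURE_NAMES,
    band = band,
    class = c("feature_tbl", class(tibble::as_tibble(tbl)))
  )
}

#' Column provenance of a feature table
#'
#' Maps every feature column to its `(channel, feature)` pair, in table
#' order. Works from the table's attributes when present, otherwise by
#' parsing the `<channel>_<feature>` column names against the canonical
#' feature set.
#'
#' @param x A `feature_tbl`, or any data frame with canonical feature
#'   columns, or a character vector of column names.
#' @return Tibble with columns `column`, `channel`, `feature`.
#' @export
feature_column_index <- function(x) {
  cols <- if (is.character(x)) x else setdiff(names(x), c("subject", "window"))
  pat <- paste0("_(", paste(FEATURE_NAMES, collapse = "|"), ")$")
  hit <- regexpr(pat, cols)
  if (any(hit < 0L)) {
    abort("Columns lack the <channel>_<feature> naming needed for channel grouping.",
          class = "eegauth_contract_error")
  }
  tibble::tibble(
    column = cols,
    channel = substr(cols, 1L, hit - 1L),
    feature = substring(cols, hit + 1L)
  )
}

#' Extract per-band feature tables for a whole cohort
#'
#' Runs the preprocessing front end for every subject: overall-band
#' zero-phase filtering, sub-band extraction, windowing and feature
#' computation, then stacks subjects row-wise per band.
#'
#' @param cohort List of [eeg_recording()]s.
#' @param bands Bands to keep (default all six).
#' @param wspec A [window_spec()].
#' @return Named list of `feature_tbl`s, one per requested band.
#' @export
extract_cohort_features <- function(cohort, bands = BAND_NAMES,
                                    wspec = window_spec()) {
  bands <- match.arg(bands, BAND_NAMES, several.ok = TRUE)
  defs <- band_definitions()
  overall <- defs[defs$band == "overall", ]
  per_subject <- lapply(cohort, function(rec) {
    filtered <- bandpass_filter(
      rec, filter_spec(overall$f_low, overall$f_high, overall$order, rec$fs)
    )
    all_bands <- extract_bands(filtered, bands = bands)
    lapply(all_bands, build_feature_table, wspec = wspec)
  })
  stats::setNames(lapply(bands, function(b) {
    tabs <- lapply(per_subject, `[[`, b)
    stacked <- dplyr::bind_rows(tabs)
    new_feature_tbl(stacked,
                    channel_labels = attr(tabs[[1]], "channel_labels"),
                    band = b)
  }), bands)
}
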