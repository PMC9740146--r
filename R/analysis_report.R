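bundles_for_band <- function(cr, band) {
  hits <- Filter(function(b) identical(b$band, band), cr)
  if (length(hits) == 0L) {
    abort(sprintf("No bundles for band '%s'.", band), class = "eegauth_key_error")
  }
  hits
}

accuracy_curve <- function(bundle) {
  tibble::tibble(n_channels = bundle$steps$n_channels,
                 accuracy = bundle$steps$accuracy)
}

#' Subject-averaged accuracy curve for one band
#'
#' Element-wise mean accuracy across subjects at each channel count.
#'
#' @param cr A [cohort_results()].
#' @param band Band name.
#' @return Tibble with `n_channels` (decreasing) and `accuracy`.
#' @export
average_band_accuracy <- function(cr, band) {
  hits <- bundles_for_band(cr, band)
  curves <- dplyr::bind_rows(lapply(hits, accuracy_curve))
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(curves, .data$n_channels),
                     accuracy = mean(.data$accuracy), .groups = "drop"),
    dplyr::desc(.data$n_channels)
  )
}

#' Per-step change in accuracy for one run
#'
#' The accuracy delta caused by each successive channel removal:
#' `delta[i] = accuracy(step i+1) - accuracy(step i)` walking down the
#' ablation, so the deltas telescope to last minus first accuracy.
#'
#' @param bundle An [auth_results()].
#' @return Tibble with `n_channels` (the count after the removal), `removed`
#'   and `delta`.
#' @export
change_in_accuracy <- function(bundle) {
  s <- bundle$steps
  if (nrow(s) < 2L) {
    return(tibble::tibble(n_channels = integer(), removed = character(),
                          delta = numeric()))
  }
  tibble::tibble(
    n_channels = s$n_channels[-1L],
    removed = s$removed[-nrow(s)],
    delta = diff(s$accuracy)
  )
}

#' Subject-averaged channel importance for one band
#'
#' Mean of the per-subject impurity importance fractions, renormalized to
#' sum to 1.
#'
#' @param cr A [cohort_results()].
#' @param band Band name.
#' @return Tibble with `channel` and `importance`, descending.
#' @export
average_importance_by_band <- function(cr, band) {
  hits <- bundles_for_band(cr, band)
  imp <- dplyr::bind_rows(lapply(hits, function(b) {
    tibble::tibble(channel = b$ranking$channel,
                   importance = b$ranking$importance)
  }))
  out <- dplyr::summarise(dplyr::group_by(imp, .data$channel),
                          importance = mean(.data$importance),
                          .groups = "drop")
  out$importance <- out$importance / sum(out$importance)
  dplyr::arrange(out, dplyr::desc(.data$importance))
}

#' How often each channel ranks in the top k
#'
#' For every (subject, band) ranking in the requested bands, marks the `k`
#' highest-importance channels and counts, per channel, how many rankings
#' include it — the montage-design membership table.
#'
#' @param cr A [cohort_results()].
#' @param k Top-list size (default 14); at most the channel count.
#' @param bands Bands whose rankings are counted (default the three
#'   best-performing: gamma, beta, overall).
#' @return Tibble with `channel` and integer `count` in
#'   `[0, n_subjects * n_bands]`, sorted by decreasing count then label.
#' @export
top_k_membership_counts <- function(cr, k = 14L,
                                    bands = c("gamma", "beta", "overall")) {
  hits <- unlist(lapply(bands, function(b) bundles_for_band(cr, b)),
                 recursive = FALSE)
  channels <- sort(hits[[1]]$ranking$channel)
  if (k > length(channels)) {
    abort("`k` exceeds the channel count.", class = "eegauth_parameter_error")
  }
  counts <- stats::setNames(integer(length(channels)), channels)
  for (b in hits) {
    top <- b$ranking$channel[seq_len(k)]
    counts[top] <- counts[top] + 1L
  }
  out <- tibble::tibble(channel = names(counts), count = as.integer(counts))
  dplyr::arrange(out, dplyr::desc(.data$count), .data$channel)
}

#' Overall top-k channel list
#'
#' Channels ordered by how often they appear in the individual top-k lists
#' across the given bands; ties break by mean importance over those bands'
#' rankings, then by label.
#'
#' @inheritParams top_k_membership_counts
#' @return Character vector of the `k` selected channel labels.
#' @export
overall_top_channels <- function(cr, k = 14L,
                                 bands = c("gamma", "beta", "overall")) {
  counts <- top_k_membership_counts(cr, k = k, bands = bands)
  hits <- unlist(lapply(bands, function(b) bundles_for_band(cr, b)),
                 recursive = FALSE)
  imp <- dplyr::bind_rows(lapply(hits, function(b) {
    tibble::tibble(channel = b$ranking$channel,
                   importance = b$ranking$importance)
  }))
  mean_imp <- dplyr::summarise(dplyr::group_by(imp, .data$channel),
                               mean_importance = mean(.data$importance),
                               .groups = "drop")
  merged <- dplyr::left_join(counts, mean_imp, by = "channel")
  merged <- dplyr::arrange(merged, dplyr::desc(.data$count),
                           dplyr::desc(.data$mean_importance), .data$channel)
  merged$channel[seq_len(k)]
}

#' Minimum-channel table across bands
#'
#' Applies the 1-percentage-point criterion to each band's subject-averaged
#' accuracy curve, with the averaged full-montage accuracy as benchmark.
#'
#' @param cr A [cohort_results()].
#' @param tolerance Percentage points of allowed loss (default 1).
#' @return Tibble with `band` and `min_channels`.
#' @export
min_channels_table <- function(cr, tolerance = 1) {
  bands <- unique(vapply(cr, function(b) b$band, ""))
  dplyr::bind_rows(lapply(bands, function(b) {
    curve <- average_band_accuracy(cr, b)
    tibble::tibble(
      band = b,
      min_channels = min_channels_before_drop(curve, curve$accuracy[1],
                                              tolerance = tolerance)
    )
  }))
}

#' Acquisition data rate of an EEG montage
#'
#' Samples per second across all electrodes (`n_electrodes * fs`) and, when
#' a bit depth is given, the raw bit rate: 14 electrodes at 128 Hz stream
#' 1792 samples/s, and a 16-bit, 64-electrode system at 512 Hz produces
#' 32,768 samples/s, i.e. 524,288 bits/s.
#'
#' @param n_electrodes Electrode count.
#' @param fs Sampling rate in Hz.
#' @param bit_depth Optional ADC resolution in bits per sample.
#' @return Tibble with `samples_per_second` and `bits_per_second`
#'   (`NA` when no bit depth is given).
#' @export
#' @examples
#' data_rate(14, 128)
#' data_rate(64, 512, bit_depth = 16)
data_rate <- function(n_electrodes, fs, bit_depth = NULL) {
  if (n_electrodes < 1 || fs <= 0) {
    abort("Electrode count and sampling rate must be positive.",
          class = "eegauth_domain_error")
  }
  sps <- n_electrodes * fs
  tibble::tibble(
    samples_per_second = sps,
    bits_per_second = if (is.null(bit_depth)) NA_real_ else sps * bit_depth
  )
}

#' Subject-averaged classification time per channel count
#'
#' Descriptive only: wall-clock times are hardware-dependent and carry no
#' accuracy semantics.
#'
#' @param cr A [cohort_results()].
#' @param band Band name.
#' @return Tibble with `n_channels` (decreasing) and `classify_time`
#'   (mean seconds).
#' @export
timing_summary <- function(cr, band) {
  hits <- bundles_for_band(cr, band)
  times <- dplyr::bind_rows(lapply(hits, function(b) {
    tibble::tibble(n_channels = b$steps$n_channels,
                   classify_time = b$steps$classify_time)
  }))
  dplyr::arrange(
    dplyr::summarise(dplyr::group_by(times, .data$n_channels),
                     classify_time = mean(.data$classify_time),
                     .groups = "drop"),
    dplyr::desc(.data$n_channels)
  )
}
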