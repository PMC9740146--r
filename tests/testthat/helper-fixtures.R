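# shared fixture builders; everything is generated in code at test time

sine_recording <- function(freq, fs = 500, duration = 4, amplitude = 1,
                           n_channels = 1L, subject_id = 1L) {
  t <- (seq_len(round(duration * fs)) - 1L) / fs
  x <- amplitude * sin(2 * pi * freq * t)
  eeg_recording(matrix(rep(x, each = n_channels), nrow = n_channels),
                fs = fs, subject_id = subject_id)
}

# small cohort with strong, planted signatures: cheap and near-separable
strong_cohort_spec <- function(n_subjects = 4L, n_channels = 8L,
                               duration = 8, seed = 11L) {
  cohort_spec(
    n_subjects = n_subjects, n_channels = n_channels, fs = 500,
    duration = duration, seed = seed, informative = 1:3,
    signature_levels = c(0.4, 1.6), noise_scale = 0.2
  )
}

# feature table drawn from random data, for split/SMOTE plumbing tests
random_feature_table <- function(n_subjects = 3L, windows_per_subject = 40L,
                                 n_channels = 2L, seed = 1L) {
  withr::with_seed(seed, {
    n <- n_subjects * windows_per_subject
    p <- n_channels * length(feature_names())
    mat <- matrix(rnorm(n * p), n, p)
    labels <- if (n_channels <= 32L) {
      montage_32()[seq_len(n_channels)]
    } else {
      sprintf("Ch%02d", seq_len(n_channels))
    }
    colnames(mat) <- as.vector(t(outer(labels, feature_names(), paste, sep = "_")))
    tbl <- dplyr::bind_cols(
      tibble::tibble(
        subject = rep(seq_len(n_subjects), each = windows_per_subject),
        window = rep(seq_len(windows_per_subject), n_subjects)
      ),
      tibble::as_tibble(as.data.frame(mat))
    )
    eegauth:::new_feature_tbl(tbl, channel_labels = labels, band = "gamma")
  })
}

# fraction of a signal's periodogram power inside [f_lo, f_hi]
in_band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  P <- P[2:(floor(n / 2) + 1)]
  f <- seq_len(floor(n / 2)) * fs / n
  sum(P[f >= f_lo & f <= f_hi]) / sum(P)
}
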