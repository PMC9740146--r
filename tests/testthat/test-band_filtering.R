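test_that("normalized frequency maps cutoffs onto (0, 1]", {
  expect_equal(normalized_frequency(50, 500), 0.2)
  expect_equal(normalized_frequency(0.2, 500), 0.0008)
  expect_equal(normalized_frequency(250, 500), 1.0)
  expect_error(normalized_frequency(260, 500), class = "eegauth_domain_error")
  expect_error(normalized_frequency(0, 500), class = "eegauth_domain_error")
})

test_that("band table carries the five sub-bands and the delta order exception", {
  defs <- band_definitions()
  expect_identical(defs$band,
                   c("overall", "delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(defs$f_low, c(0.2, 0.2, 4, 8, 12, 26))
  expect_equal(defs$f_high, c(50, 4, 8, 12, 26, 50))
  expect_identical(defs$order, c(4L, 2L, 4L, 4L, 4L, 4L))
})

test_that("overall-band filter passes a mid-band sine and kills a stopband sine", {
  # the 0.2 Hz high-pass edge rings for ~2 s, so the fixture is long enough
  # for its central 80% to sit clear of the (padded) edge transients
  overall <- filter_spec(0.2, 50, 4, 500)

  rec25 <- sine_recording(25, duration = 60)
  out <- bandpass_filter(rec25, overall)
  n <- ncol(out$data)
  central <- out$data[1, round(0.1 * n):round(0.9 * n)]
  expect_lt(abs(max(abs(central)) - 1), 0.01)      # passband amplitude ~1

  rec100 <- sine_recording(100, duration = 60)
  out100 <- bandpass_filter(rec100, overall)
  central100 <- out100$data[1, round(0.1 * n):round(0.9 * n)]
  expect_lt(sqrt(mean(central100^2)), 0.01)        # stopband RMS < 1%
})

test_that("zero input gives zero output and shape/labels are preserved", {
  rec <- eeg_recording(matrix(0, 3, 2000), fs = 500,
                       channel_labels = c("Fp1", "Cz", "O2"), subject_id = 4L)
  out <- bandpass_filter(rec, filter_spec(0.2, 50, 4, 500))
  expect_equal(out$data, matrix(0, 3, 2000))
  expect_identical(dim(out$data), dim(rec$data))
  expect_identical(out$channel_labels, rec$channel_labels)
  expect_identical(out$subject_id, rec$subject_id)
})

test_that("filtering is linear and zero-phase", {
  spec <- filter_spec(8, 12, 4, 500)
  withr::with_seed(3, {
    x <- rnorm(3000)
    y <- rnorm(3000)
  })
  as_rec <- function(v) eeg_recording(matrix(v, 1), fs = 500,
                                      channel_labels = "Cz")
  f <- function(v) bandpass_filter(as_rec(v), spec)$data[1, ]
  expect_equal(f(2 * x - 3 * y), 2 * f(x) - 3 * f(y), tolerance = 1e-9)

  # mid-band sine: cross-correlation between input and output peaks at lag 0
  rec <- sine_recording(10)
  out <- bandpass_filter(rec, spec)
  n <- ncol(rec$data)
  core <- round(0.2 * n):round(0.8 * n)
  lags <- -5:5
  cc <- vapply(lags, function(l) {
    sum(rec$data[1, core] * out$data[1, core + l])
  }, 0)
  expect_equal(lags[which.max(cc)], 0)
})

test_that("each sub-band concentrates a mid-band sine's power in-band", {
  defs <- band_definitions()
  sub <- defs[defs$band != "overall", ]
  for (i in seq_len(nrow(sub))) {
    fmid <- sqrt(sub$f_low[i] * sub$f_high[i])   # geometric band centre
    rec <- sine_recording(fmid, duration = 8)
    out <- bandpass_filter(
      rec, filter_spec(sub$f_low[i], sub$f_high[i], sub$order[i], 500)
    )
    frac <- in_band_power_fraction(out$data[1, ], 500, sub$f_low[i], sub$f_high[i])
    expect_gt(frac, 0.9)
  }
})

test_that("band extraction returns all six bands with the delta exception applied", {
  rec <- sine_recording(30, duration = 4)
  bands <- extract_bands(rec)
  expect_identical(names(bands),
                   c("overall", "delta", "theta", "alpha", "beta", "gamma"))
  expect_true(all(vapply(bands, function(b) {
    identical(dim(b$data), dim(rec$data))
  }, TRUE)))
  expect_identical(attr(bands$delta, "band_definition")$order, 2L)
  expect_identical(attr(bands$gamma, "band_definition")$order, 4L)

  # 30 Hz sine: gamma keeps >= 90% of the amplitude, alpha kills it
  n <- ncol(rec$data)
  core <- round(0.1 * n):round(0.9 * n)
  expect_gt(max(abs(bands$gamma$data[1, core])), 0.9)
  rms_in <- sqrt(mean(rec$data[1, core]^2))
  expect_lt(sqrt(mean(bands$alpha$data[1, core]^2)), 0.05 * rms_in)
})

test_that("squared magnitude response matches a transfer-function design on a benign band", {
  skip_if_not_installed("signal")
  # theta band is well-conditioned in transfer-function form: the classic
  # two-pass filtfilt magnitude equals |H|^2 of the same Butterworth design
  spec <- filter_spec(4, 8, 4, 500)
  ba <- signal::butter(4, c(4, 8) / 250, type = "pass")
  rec <- sine_recording(6, duration = 8)
  out <- bandpass_filter(rec, spec)
  n <- ncol(rec$data)
  # amplitude by complex projection over whole cycles in the central span
  t_core <- (round(0.2 * n):(round(0.2 * n) + 2499)) / 500
  y <- out$data[1, round(0.2 * n):(round(0.2 * n) + 2499)]
  gain2 <- 2 * Mod(mean(y * exp(-2i * pi * 6 * t_core)))
  H <- function(f) {
    z <- exp(1i * 2 * pi * f / 500)
    abs(sum(ba$b * z^-(0:8)) / sum(ba$a * z^-(0:8)))
  }
  expect_equal(gain2, H(6)^2, tolerance = 1e-3)
})

test_that("too-short signals raise a length error", {
  rec <- eeg_recording(matrix(rnorm(20), 1, 20), fs = 500,
                       channel_labels = "Cz")
  expect_error(bandpass_filter(rec, filter_spec(0.2, 50, 4, 500)),
               class = "eegauth_length_error")
})
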