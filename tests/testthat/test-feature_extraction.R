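test_that("window counts follow the floor formula", {
  # 2.0 s at 500 Hz, 0.5 s / 0.25 s windows: floor((1000-250)/125)+1 = 7
  rec <- eeg_recording(matrix(rnorm(1000), 1, 1000), fs = 500,
                       channel_labels = "Cz")
  wins <- window_signal(rec, window_spec())
  expect_length(wins, 7L)
  expect_true(all(vapply(wins, ncol, 0L) == 250L))

  rec1 <- eeg_recording(matrix(rnorm(250), 1, 250), fs = 500,
                        channel_labels = "Cz")
  expect_length(window_signal(rec1, window_spec()), 1L)

  rec_short <- eeg_recording(matrix(rnorm(200), 1, 200), fs = 500,
                             channel_labels = "Cz")
  expect_warning(wins0 <- window_signal(rec_short, window_spec()))
  expect_length(wins0, 0L)
})

test_that("degenerate windows hit the documented guard values", {
  f <- compute_features(rep(5, 250), fs = 500)
  expect_equal(f[["mean"]], 5)
  expect_equal(f[["sd"]], 0)
  expect_equal(f[["mav"]], 5)
  expect_equal(f[["rms"]], 5)
  expect_equal(f[["skewness"]], 0)
  expect_equal(f[["kurtosis"]], 0)
  expect_equal(f[["activity"]], 0)
  expect_equal(f[["mobility"]], 0)
  expect_equal(f[["complexity"]], 0)
  expect_equal(f[["shannon_entropy"]], 0)

  alt <- compute_features(rep(c(1, -1), 125), fs = 500)
  expect_equal(alt[["mean"]], 0)
  expect_equal(alt[["mav"]], 1)
  expect_equal(alt[["rms"]], 1)

  expect_error(compute_features(c(1, 2, NaN), fs = 500),
               class = "eegauth_validation_error")
})

test_that("moment and entropy features match statistical expectations", {
  withr::with_seed(9, x <- rnorm(4096))
  f <- compute_features(x, fs = 500)
  expect_lt(abs(f[["kurtosis"]] - 3), 0.3)       # Gaussian, non-excess
  expect_gt(f[["spectral_entropy"]], 0.9)        # broadband noise

  tone <- sin(2 * pi * 20 * (0:249) / 500)
  ft <- compute_features(tone, fs = 500)
  expect_lt(ft[["spectral_entropy"]], 0.3)       # tonal concentration
})

test_that("Hjorth features match an independent finite-difference oracle", {
  # oracle built from explicit loops over the textbook variance ratios
  hjorth_oracle <- function(x) {
    pv <- function(z) {
      m <- sum(z) / length(z)
      s <- 0
      for (v in z) s <- s + (v - m)^2
      s / length(z)
    }
    d1 <- x[-1] - x[-length(x)]
    d2 <- d1[-1] - d1[-length(d1)]
    act <- pv(x)
    mob <- sqrt(pv(d1) / act)
    comp <- sqrt(pv(d2) / pv(d1)) / mob
    c(act, mob, comp)
  }
  withr::with_seed(21, {
    for (i in 1:100) {
      x <- rnorm(64) * runif(1, 0.1, 10)
      f <- compute_features(x, fs = 500)
      o <- hjorth_oracle(x)
      expect_equal(f[["activity"]], o[1], tolerance = 1e-9)
      expect_equal(f[["mobility"]], o[2], tolerance = 1e-9)
      expect_equal(f[["complexity"]], o[3], tolerance = 1e-9)
    }
  })
})

test_that("features scale as documented under amplitude scaling", {
  withr::with_seed(13, x <- rnorm(250))
  c_ <- 3.7
  f1 <- compute_features(x, fs = 500)
  f2 <- compute_features(c_ * x, fs = 500)
  expect_equal(f2[["mean"]], c_ * f1[["mean"]], tolerance = 1e-12)
  expect_equal(f2[["sd"]], c_ * f1[["sd"]], tolerance = 1e-12)
  expect_equal(f2[["mav"]], c_ * f1[["mav"]], tolerance = 1e-12)
  expect_equal(f2[["rms"]], c_ * f1[["rms"]], tolerance = 1e-12)
  expect_equal(f2[["activity"]], c_^2 * f1[["activity"]], tolerance = 1e-12)
  for (nm in c("skewness", "kurtosis", "mobility", "complexity",
               "spectral_entropy")) {
    expect_equal(f2[[nm]], f1[[nm]], tolerance = 1e-9)
  }
})

test_that("feature values stay finite on adversarial finite inputs", {
  cases <- list(
    rep(0, 16), rep(1e-300, 16), rep(1e300, 8),
    c(rep(0, 15), 1), seq(0, 1, length.out = 32),
    rep(c(0, 0, 1e-12), 11)
  )
  withr::with_seed(77, {
    for (i in 1:20) cases[[length(cases) + 1]] <- rnorm(16, sd = 10^runif(1, -6, 6))
  })
  for (x in cases) {
    expect_true(all(is.finite(compute_features(x, fs = 100))))
  }
})

test_that("feature tables are channel-major and agree with per-window computation", {
  withr::with_seed(4, {
    rec <- eeg_recording(matrix(rnorm(3 * 1000), 3, 1000), fs = 500,
                         channel_labels = c("Fp1", "Cz", "O2"),
                         subject_id = 6L)
  })
  ft <- build_feature_table(rec, window_spec(), band = "overall")
  expect_equal(nrow(ft), 7L)
  expect_equal(ncol(ft), 2L + 3L * 11L)
  expect_true(all(ft$subject == 6L))

  idx <- feature_column_index(ft)
  expect_identical(unique(idx$channel), c("Fp1", "Cz", "O2"))  # channel-major
  expect_identical(idx$feature[1:11], feature_names())

  # vectorized table values equal the scalar per-window feature op
  wins <- window_signal(rec, window_spec())
  for (w in c(1L, 4L, 7L)) {
    for (ch in 1:3) {
      expected <- compute_features(wins[[w]][ch, ], fs = 500)
      got <- as.numeric(ft[w, paste(rec$channel_labels[ch], feature_names(),
                                    sep = "_")])
      expect_equal(got, unname(expected), tolerance = 1e-12)
    }
  }
})
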