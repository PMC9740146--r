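# build a cohort_results fixture from hand-written curves/rankings
mk_bundle <- function(subject, band, accs, importances, channels) {
  C <- length(channels)
  rk <- channel_ranking(importances, channels, subject, band)
  used <- lapply(seq(C, 1), function(n) rk$channel[seq_len(n)])
  steps <- tibble::tibble(
    n_channels = seq(C, 1),
    channels_used = used,
    removed = c(vapply(seq_len(C - 1), function(i) {
      setdiff(used[[i]], used[[i + 1]])
    }, ""), NA),
    accuracy = accs,
    train_time = rep(0.5, C),
    classify_time = rep(0.25, C)
  )
  auth_results(subject, band, rk, steps, tuned_params = list(n_trees = 10))
}

chs <- c("Fp1", "Fp2", "Cz", "O2")

test_that("band-averaged accuracy is the element-wise subject mean", {
  c1 <- c(0.9, 0.9, 0.8, 0.7)
  b1 <- mk_bundle(1, "gamma", c1, c(4, 3, 2, 1), chs)
  b2 <- mk_bundle(2, "gamma", c1 + 0.1, c(1, 2, 3, 4), chs)
  cr <- cohort_results(list(b1, b2))

  expect_equal(average_band_accuracy(cohort_results(list(b1)), "gamma")$accuracy, c1)
  avg <- average_band_accuracy(cr, "gamma")
  expect_equal(avg$accuracy, c1 + 0.05)
  expect_equal(avg$n_channels, 4:1)
  # permutation invariance in subject order
  expect_equal(average_band_accuracy(cohort_results(list(b2, b1)), "gamma"), avg)
  expect_error(average_band_accuracy(cr, "delta"), class = "eegauth_key_error")
})

test_that("accuracy deltas telescope to last minus first", {
  flat <- mk_bundle(1, "beta", rep(0.8, 4), c(4, 3, 2, 1), chs)
  expect_true(all(change_in_accuracy(flat)$delta == 0))

  withr::with_seed(2, accs <- c(0.9, runif(3)))
  rnd <- mk_bundle(1, "beta", accs, c(4, 3, 2, 1), chs)
  d <- change_in_accuracy(rnd)
  expect_equal(sum(d$delta), accs[4] - accs[1])
  expect_equal(d$n_channels, 3:1)

  dec <- mk_bundle(1, "beta", c(0.9, 0.8, 0.7, 0.6), c(4, 3, 2, 1), chs)
  expect_true(all(change_in_accuracy(dec)$delta < 0))
})

test_that("band-averaged importance renormalizes to one", {
  b1 <- mk_bundle(1, "gamma", rep(0.9, 4), c(0.4, 0.3, 0.2, 0.1), chs)
  b2 <- mk_bundle(2, "gamma", rep(0.9, 4), c(0.4, 0.3, 0.2, 0.1), chs)
  same <- average_importance_by_band(cohort_results(list(b1, b2)), "gamma")
  expect_equal(same$importance, c(0.4, 0.3, 0.2, 0.1))
  expect_equal(sum(same$importance), 1)

  # disjoint one-hot rankings over 2 subjects average to 0.5/0.5
  h1 <- mk_bundle(1, "beta", rep(0.9, 2), c(1, 0), c("Fp1", "Fp2"))
  h2 <- mk_bundle(2, "beta", rep(0.9, 2), c(0, 1), c("Fp1", "Fp2"))
  half <- average_importance_by_band(cohort_results(list(h1, h2)), "beta")
  expect_equal(sort(half$importance), c(0.5, 0.5))
})

test_that("top-k membership counts satisfy the pigeonhole identity", {
  imp <- list(c(4, 3, 2, 1), c(1, 4, 3, 2), c(2, 1, 4, 3))
  bundles <- list()
  for (s in 1:3) {
    for (b in c("gamma", "beta", "overall")) {
      bundles[[length(bundles) + 1]] <- mk_bundle(s, b, rep(0.9, 4), imp[[s]], chs)
    }
  }
  cr <- cohort_results(bundles)
  for (k in 1:4) {
    counts <- top_k_membership_counts(cr, k = k)
    expect_equal(sum(counts$count), k * 9L)          # k x number of lists
    expect_true(all(counts$count >= 0 & counts$count <= 9L))
  }
  full <- top_k_membership_counts(cr, k = 4)
  expect_true(all(full$count == 9L))                 # k = channel count

  shared <- cohort_results(lapply(1:3, function(s) {
    mk_bundle(s, "gamma", rep(0.9, 4), c(4, 3, 2, 1), chs)
  }))
  counts2 <- top_k_membership_counts(shared, k = 2, bands = "gamma")
  expect_equal(counts2$count[counts2$channel %in% c("Fp1", "Fp2")], c(3L, 3L))
  expect_equal(sum(counts2$count[!counts2$channel %in% c("Fp1", "Fp2")]), 0L)

  expect_error(top_k_membership_counts(cr, k = 5),
               class = "eegauth_parameter_error")
})

test_that("overall top list breaks ties by mean importance then label", {
  b1 <- mk_bundle(1, "gamma", rep(0.9, 4), c(4, 3, 2, 1), chs)
  b2 <- mk_bundle(1, "beta", rep(0.9, 4), c(4, 3, 2, 1), chs)
  b3 <- mk_bundle(1, "overall", rep(0.9, 4), c(4, 3, 2, 1), chs)
  top <- overall_top_channels(cohort_results(list(b1, b2, b3)), k = 2)
  expect_equal(top, c("Fp1", "Fp2"))
})

test_that("minimum-channel table applies the rule to averaged curves", {
  b1 <- mk_bundle(1, "gamma", c(0.9, 0.9, 0.893, 0.8), c(4, 3, 2, 1), chs)
  b2 <- mk_bundle(2, "gamma", c(0.9, 0.9, 0.893, 0.8), c(4, 3, 2, 1), chs)
  d1 <- mk_bundle(1, "delta", c(0.9, 0.88, 0.88, 0.88), c(4, 3, 2, 1), chs)
  cr <- cohort_results(list(b1, b2, d1))
  tab <- min_channels_table(cr)
  expect_equal(tab$min_channels[tab$band == "gamma"], 2L)
  expect_equal(tab$min_channels[tab$band == "delta"], 4L)

  # zero tolerance returns the full count on a strictly decreasing curve
  dec <- mk_bundle(1, "theta", c(0.9, 0.85, 0.8, 0.75), c(4, 3, 2, 1), chs)
  tab0 <- min_channels_table(cohort_results(list(dec)), tolerance = 0)
  expect_equal(tab0$min_channels, 4L)
})

test_that("montage data rates multiply out and carry optional bit depth", {
  expect_equal(data_rate(14, 128)$samples_per_second, 1792)
  r <- data_rate(64, 512, bit_depth = 16)
  expect_equal(r$samples_per_second, 32768)
  expect_equal(r$bits_per_second, 524288)
  expect_equal(data_rate(1, 1)$samples_per_second, 1)
  expect_true(is.na(data_rate(2, 100)$bits_per_second))
})

test_that("timing summaries average recorded classification times", {
  b1 <- mk_bundle(1, "gamma", rep(0.9, 4), c(4, 3, 2, 1), chs)
  b2 <- mk_bundle(2, "gamma", rep(0.9, 4), c(4, 3, 2, 1), chs)
  ts1 <- timing_summary(cohort_results(list(b1)), "gamma")
  expect_equal(ts1$classify_time, b1$steps$classify_time)
  ts <- timing_summary(cohort_results(list(b1, b2)), "gamma")
  expect_equal(nrow(ts), 4L)
  expect_equal(ts$classify_time, rep(0.25, 4))
})

test_that("tidiers and plots expose the bundle as tables and ggplots", {
  b <- mk_bundle(3, "gamma", c(0.9, 0.9, 0.85, 0.7), c(4, 3, 2, 1), chs)
  td <- tidy(b)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$accuracy, b$steps$accuracy)
  gl <- glance(b)
  expect_equal(gl$benchmark_accuracy, 0.9)
  expect_equal(gl$min_channels, 3L)
  expect_equal(gl$top_channel, "Fp1")
  expect_s3_class(autoplot(b), "ggplot")
  expect_s3_class(autoplot(b$ranking), "ggplot")
  expect_s3_class(plot_band_accuracy(cohort_results(list(b))), "ggplot")
})
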