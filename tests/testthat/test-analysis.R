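# Welch spectra, dominant frequency, epoch slicing and modulation maps.

test_that("the PSD of a pure sine peaks at the sine frequency", {
  fs <- 500
  t <- (0:(60 * fs - 1)) / fs
  est <- estimate_psd(sin(2 * pi * 10 * t), fs)
  expect_s3_class(est, "spectral_estimate")
  expect_equal(dominant_frequency(est, 1, 50), 10, tolerance = 0.5 / 10)
  expect_true(all(est$power >= 0))
  expect_true(all(diff(est$freq_hz) > 0))
})

test_that("a zero signal has an identically zero PSD", {
  est <- estimate_psd(numeric(5000), 500)
  expect_true(all(est$power == 0))
})

test_that("white noise satisfies the Parseval identity within 10%", {
  set.seed(8)
  fs <- 500
  sigma <- 0.7
  x <- rnorm(60 * fs, sd = sigma)
  est <- estimate_psd(x, fs)
  integrated <- sum(est$power) * fs / attr(est, "segment_len")
  expect_equal(integrated, sigma^2, tolerance = 0.1)
})

test_that("Parseval consistency holds for arbitrary signals", {
  set.seed(42)
  fs <- 250
  for (i in 1:3) {
    x <- stats::filter(rnorm(20 * fs), rep(1 / 4, 4), sides = 1)
    x[is.na(x)] <- 0
    x <- as.numeric(x)
    est <- estimate_psd(x, fs, segment_len = 500, overlap_frac = 0)
    integrated <- sum(est$power) * fs / 500
    # mean square of the windowed segments, matched to the estimator's scaling
    w <- 0.5 - 0.5 * cos(2 * pi * (0:499) / 499)
    starts <- seq(1, length(x) - 499, by = 500)
    msq <- mean(vapply(starts, function(s) {
      mean((x[s:(s + 499)] * w)^2) * 500 / sum(w^2)
    }, numeric(1)))
    expect_equal(integrated, msq, tolerance = 0.01)
  }
})

test_that("dominant_frequency honours the band and breaks ties downward", {
  est <- structure(
    tibble::tibble(freq_hz = c(2, 4, 8, 12, 16), power = c(1, 2, 5, 5, 3)),
    class = c("spectral_estimate", class(tibble::tibble())))
  expect_equal(dominant_frequency(est, 0, 20), 8)   # tie at 8 and 12
  expect_equal(dominant_frequency(est, 10, 20), 12) # band excludes the tie
  expect_error(dominant_frequency(est, 30, 40), class = "phasestim_data_error")
  expect_error(estimate_psd(rnorm(10), 500), class = "phasestim_data_error")
})

test_that("epoch slices are head-trimmed, condition-labelled and cover the log", {
  cfg <- quick_loop_config(gain = 8, on_s = 4, off_s = 4, seed = 3)
  log <- run_session(cfg)
  fs <- log$header$fs_channel_hz
  slices <- epoch_slices(log, trim_s = 1)
  expect_equal(nrow(slices), 4)  # 2 stim + 2 control epochs
  expect_equal(sum(!slices$is_control), 2)
  # each 4 s epoch loses 1 s of samples at the channel rate
  expect_true(all(slices$n_samples == 4 * fs - 1 * fs))
  # trims + slices partition the control-channel series
  total <- nrow(log$packets[log$packets$channel == 0L, ])
  expect_equal(sum(slices$n_samples) + nrow(slices) * fs, total)
  # no trim: slices alone cover everything
  full <- epoch_slices(log, trim_s = 0)
  expect_equal(sort(unlist(full$idx)), seq_len(total))
})

test_that("a zero-gain session yields a near-flat modulation map", {
  cfg <- loop_config(
    seed = 5,
    conditions = default_phase_grid(gain = 0),
    planner = planner_config(on_duration_s = 60, off_duration_s = 60))
  log <- run_session(cfg)
  map <- modulation_map(log, f_min = 5, f_max = 20)
  expect_lt(max(abs(map$modulation_db)), 3)
  # most cells well inside +/-1 dB
  expect_gt(mean(abs(map$modulation_db) < 1), 0.8)
})

test_that("the tiled phase axis duplicates the map exactly over two cycles", {
  cfg <- quick_loop_config(gain = 8, on_s = 4, off_s = 4, seed = 2)
  log <- run_session(cfg)
  map <- modulation_map(log, f_min = 5, f_max = 20, two_cycles = TRUE)
  one <- map[map$phase_deg < 360, ]
  two <- map[map$phase_deg >= 360, ]
  expect_equal(max(map$phase_deg), max(one$phase_deg) + 360)
  key <- function(d) d[order(d$freq_hz, d$phase_deg %% 360), "modulation_db"]
  expect_equal(key(two), key(one))
})

test_that("permuting condition labels permutes map columns identically", {
  cfg <- quick_loop_config(gain = 8, on_s = 4, off_s = 4, seed = 4)
  log <- run_session(cfg)
  map <- modulation_map(log, f_min = 5, f_max = 20, two_cycles = FALSE)
  # relabel: swap condition ids 1 and 2 in packets and conditions
  log2 <- log
  swap <- c(`1` = 2L, `2` = 1L)
  log2$packets$condition_id <- ifelse(
    is.na(log$packets$condition_id), NA_integer_,
    swap[as.character(log$packets$condition_id)])
  log2$header$config$conditions$condition_id <- swap[
    as.character(log$header$config$conditions$condition_id)]
  map2 <- modulation_map(log2, f_min = 5, f_max = 20, two_cycles = FALSE)
  # same (phase -> spectrum) association, permuted condition ids
  m1 <- map[order(map$phase_deg, map$freq_hz), ]
  m2 <- map2[order(map2$phase_deg, map2$freq_hz), ]
  expect_equal(m2$modulation_db, m1$modulation_db)
  expect_false(identical(m1$condition_id, m2$condition_id))
})

test_that("modulation mapping requires control epochs", {
  cfg <- quick_loop_config(gain = 8, on_s = 4, off_s = 0)
  log <- run_session(cfg)
  expect_error(modulation_map(log), class = "phasestim_data_error")
})

test_that("the emulated bench stability check finds the 10 Hz input", {
  st <- stability_test(duration_s = 30, seed = 1)
  expect_equal(st$dominant_hz, 10, tolerance = 0.5 / 10)
  expect_s3_class(st$psd, "spectral_estimate")
})

test_that("modulation extrema report both statistics coherently", {
  cfg <- quick_loop_config(gain = 8, on_s = 4, off_s = 4, seed = 6)
  log <- run_session(cfg)
  map <- modulation_map(log, f_min = 5, f_max = 20)
  pw <- modulation_extrema(map, 8, 12, statistic = "pointwise")
  bm <- modulation_extrema(map, 8, 12, statistic = "band_mean")
  expect_gte(pw$max_db, bm$max_db)
  expect_lte(pw$min_db, bm$min_db)
  expect_true(pw$phase_separation_deg >= 0 && pw$phase_separation_deg <= 180)
})
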