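# Tick-loop emulator: rate arithmetic, packet accounting, gate dominance,
# determinism, cross-implementation audits, and offline replay.

test_that("effective per-channel rate follows the alternating-channel arithmetic", {
  expect_identical(effective_channel_rate(0.001, 2), 500)
  expect_identical(effective_channel_rate(0.001, 1), 1000)
  expect_identical(effective_channel_rate(0.002, 4), 125)
})

test_that("a session emits one packet per tick with balanced channels", {
  cfg <- quick_loop_config(on_s = 0.5, off_s = 0.5)
  log <- run_session(cfg, duration_s = 1)
  p <- log$packets
  expect_equal(nrow(p), 1000)
  expect_identical(p$tick, 0:999)
  expect_true(all(diff(p$tick) == 1))
  counts <- table(p$channel)
  expect_lte(max(counts) - min(counts), 1)
})

test_that("stimulation is identically zero in control epochs and with zero gain", {
  cfg <- quick_loop_config(gain = 8, on_s = 2, off_s = 2)
  log <- run_session(cfg)
  p <- log$packets
  expect_true(all(p$stim_intensity[is.na(p$condition_id)] == 0))
  expect_true(all(p$stim_intensity >= 0))
  expect_true(any(p$stim_intensity > 0))  # the loop does actuate when ON

  g0 <- run_session(quick_loop_config(gain = 0, on_s = 2, off_s = 2))
  expect_true(all(g0$packets$stim_intensity == 0))
})

test_that("a zero-gain session equals the open-loop plant through the R chain", {
  cfg <- quick_loop_config(gain = 0, on_s = 1, off_s = 1, seed = 31)
  log <- run_session(cfg)
  # same seed substreams drive the open-loop plant simulation
  pc <- cfg$plant
  pc$rng_seed <- cfg$seed
  sim <- plant_simulate(pc, duration_s = log$header$duration_s)
  expect_identical(log$internals$plant_x, sim$x)
  # the recorded samples equal the R vectorised chain on the same LFP
  recorded <- chain_apply(sim$lfp, cfg$chain)
  expect_equal(log$packets$raw_lfp, recorded, tolerance = 1e-9)
})

test_that("the engine's controller path reproduces the R controller exactly", {
  cfg <- quick_loop_config(gain = 8, on_s = 2, off_s = 1, seed = 17)
  log <- run_session(cfg)
  ctrl <- log$packets[log$packets$channel == 0L, ]
  offset <- phasestim:::chain_dc_offset(cfg$chain)
  kern <- phasestim:::condition_kernels(cfg)
  for (ep in unique(stats::na.omit(ctrl$epoch[!is.na(ctrl$condition_id)]))) {
    rows <- ctrl[!is.na(ctrl$epoch) & ctrl$epoch == ep, ]
    cond <- rows$condition_id[1]
    cc <- controller_config(kern$kernels[[cond]],
                            gain = cfg$conditions$gain[cond],
                            output_max = cfg$controller$output_max)
    ref <- controller_apply(rows$raw_lfp - offset, cc)
    expect_equal(rows$algo_out, ref$algo_out, tolerance = 1e-9)
    expect_equal(rows$stim_intensity, ref$intensity, tolerance = 1e-9)
  }
})

test_that("actuation is causal: the plant sees stimulation delayed by loop_delay_ticks", {
  cfg <- quick_loop_config(gain = 8, on_s = 2, off_s = 1, seed = 23)
  log <- run_session(cfg)
  p <- log$packets
  n <- nrow(p)
  delay <- cfg$loop_delay_ticks
  light <- c(rep(0, delay), p$stim_intensity[seq_len(n - delay)])
  xi <- phasestim:::with_seed(phasestim:::derive_seed(cfg$seed, "plant_process"),
                              rnorm(n))
  eta <- phasestim:::with_seed(
    phasestim:::derive_seed(cfg$seed, "plant_measurement"), rnorm(n))
  redo <- phasestim:::plant_run_core(
    n_ticks = n, x0 = 0, v0 = 0,
    omega0 = 2 * pi * cfg$plant$natural_freq_hz,
    zeta = cfg$plant$damping_ratio, sigma = cfg$plant$noise_sd,
    coupling = cfg$plant$light_coupling,
    meas_sd = cfg$plant$measurement_noise_sd, dt = cfg$plant$dt_s,
    light = light, xi = xi, eta = eta)
  expect_identical(redo$x, log$internals$plant_x)
})

test_that("sessions re-run bit-identically from their own header", {
  cfg <- quick_loop_config(gain = 8, on_s = 1, off_s = 1, seed = 77)
  log <- run_session(cfg)
  again <- rerun_session(log)
  expect_identical(again$packets, log$packets)
})

test_that("session logs survive the self-describing text round trip and re-run", {
  cfg <- quick_loop_config(gain = 8, on_s = 1, off_s = 1, seed = 13)
  log <- run_session(cfg)
  path <- withr::local_tempfile(fileext = ".log")
  write_session_log(log, path)
  back <- read_session_log(path)
  expect_equal(back$packets$raw_lfp, log$packets$raw_lfp, tolerance = 1e-12)
  expect_identical(back$packets$condition_id, log$packets$condition_id)
  # the parsed header is sufficient to regenerate the identical stream
  again <- rerun_session(back)
  expect_identical(again$packets, log$packets)
})

test_that("replay of an all-zero file emits an all-zero stimulation trace", {
  fs <- 500
  zero <- tibble::tibble(time_s = (0:(fs * 4 - 1)) / fs, value = 0)
  attr(zero, "sample_rate_hz") <- fs
  cfg <- quick_loop_config(gain = 1, on_s = 2, off_s = 2)
  log <- replay_session(zero, cfg)
  expect_true(all(log$packets$stim_intensity == 0))
})

test_that("replaying a 10 Hz sine at phase 0 yields ten rectified peaks per second", {
  fs <- 500
  dur <- 20
  sine <- make_fixture("sine", duration_s = dur, fs = fs, freq_hz = 10,
                       amplitude = 0.5)
  cfg <- loop_config(
    conditions = tibble::tibble(condition_id = 1L, centre_freq_hz = 10,
                                phase_shift_deg = 0, gain = 1),
    planner = planner_config(on_duration_s = dur, off_duration_s = 0),
    controller = list(n_taps = NULL, bandwidth_hz = 6, window = "hann",
                      output_max = 10)
  )
  log <- replay_session(sine, cfg)
  stim <- log$packets$stim_intensity
  # count strictly-positive local maxima plateaus of the rectified trace
  up <- stim > 1e-6
  n_peaks <- sum(diff(up) == 1)
  expect_equal(n_peaks, 10 * dur, tolerance = 0.02)
  # two replays agree exactly
  log2 <- replay_session(sine, cfg)
  expect_identical(log2$packets, log$packets)
})

test_that("replay rejects a sample-rate mismatch", {
  bad <- make_fixture("sine", duration_s = 1, fs = 1000)
  cfg <- quick_loop_config()  # controller expects 500 Hz
  expect_error(replay_session(bad, cfg), class = "phasestim_data_error")
})

test_that("mismatched sub-config rates are configuration errors", {
  expect_error(
    loop_config(tick_period_s = 0.001, chain = chain_config(sample_rate_hz = 500)),
    class = "phasestim_config_error")
  expect_error(
    loop_config(tick_period_s = 0.001, plant = plant_config(dt_s = 0.002)),
    class = "phasestim_config_error")
  expect_error(
    loop_config(conditions = tibble::tibble(
      condition_id = 1L, centre_freq_hz = 400, phase_shift_deg = 0, gain = 1)),
    class = "phasestim_config_error")
})
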