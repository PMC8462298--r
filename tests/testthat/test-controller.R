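# FIR phase-shift kernel design and the streaming LFP-to-light controller.

test_that("opposite phase commands give elementwise-negated kernels", {
  k0 <- design_phase_shift_fir(10, 0)
  k180 <- design_phase_shift_fir(10, 180)
  expect_equal(k180$taps, -k0$taps, tolerance = 1e-12)
  k45 <- design_phase_shift_fir(10, 45)
  k225 <- design_phase_shift_fir(10, 225)
  expect_equal(k225$taps, -k45$taps, tolerance = 1e-12)
})

test_that("every commanded phase is realised at f0 after group-delay removal", {
  # oracle: brute-force DTFT of the taps, independent of frequency_response()
  for (phase in seq(0, 315, by = 45)) {
    k <- design_phase_shift_fir(10, phase, fs_hz = 500)
    h <- dtft_oracle(k$taps, 10, 500)
    measured <- (Arg(h * exp(1i * 2 * pi * 10 / 500 * k$group_delay_samples)) *
                   180 / pi) %% 360
    expect_lt(angle_diff(measured, phase), 1)
    expect_equal(Mod(h), 1, tolerance = 1e-6)
  }
})

test_that("the kernel is band-pass: unit gain at f0, strong rejection off band", {
  for (phase in c(0, 90, 270)) {
    k <- design_phase_shift_fir(10, phase)
    expect_equal(Mod(frequency_response(k, 10)), 1, tolerance = 1e-6)
    expect_lt(Mod(frequency_response(k, 10 / 4)), 0.1)
    expect_lt(Mod(frequency_response(k, 4 * 10)), 0.1)
  }
})

test_that("frequency_response matches the oracle and is Hermitian for real taps", {
  k <- design_phase_shift_fir(12, 135, fs_hz = 500, n_taps = 75)
  freqs <- c(0, 3, 12, 40, 120)
  for (f in freqs) {
    expect_equal(frequency_response(k, f), dtft_oracle(k$taps, f, 500),
                 tolerance = 1e-12)
  }
  expect_equal(frequency_response(k, -freqs), Conj(frequency_response(k, freqs)),
               tolerance = 1e-12)
  # DC response equals the tap sum by definition
  expect_equal(Mod(frequency_response(k, 0)), abs(sum(k$taps)), tolerance = 1e-12)
})

test_that("design rejects out-of-range centre frequencies and even tap counts", {
  expect_error(design_phase_shift_fir(300, 0, fs_hz = 500),
               class = "phasestim_config_error")
  expect_error(design_phase_shift_fir(10, 0, n_taps = 100),
               class = "phasestim_config_error")
})

test_that("controller_step is causal, rectifying and saturating", {
  k <- design_phase_shift_fir(10, 0)
  cc <- controller_config(k, gain = 2, output_max = 1)
  st <- controller_state(cc)
  r <- controller_step(st, 0, cc)
  expect_equal(r$algo_out, 0)
  expect_equal(r$stim$intensity, 0)
  # gain 0 silences any input
  cc0 <- controller_config(k, gain = 0)
  st <- controller_state(cc0)
  for (x in c(1, -3, 100)) {
    r <- controller_step(st, x, cc0)
    st <- r$state
    expect_equal(r$stim$intensity, 0)
  }
  # rectification + saturation over random signals
  set.seed(3)
  out <- controller_apply(rnorm(500, sd = 5), cc)
  expect_true(all(out$intensity >= 0))
  expect_true(all(out$intensity <= 1))
})

test_that("a steady sine emerges delayed by the group delay with unit amplitude", {
  fs <- 500
  k <- design_phase_shift_fir(10, 0, fs_hz = fs)
  cc <- controller_config(k, gain = 1, output_max = 10)
  t <- (0:(6 * fs)) / fs
  x <- sin(2 * pi * 10 * t)
  out <- controller_apply(x, cc)
  steady <- out$algo_out[t > 2]
  expect_equal((max(steady) - min(steady)) / 2, 1, tolerance = 0.02)
  # delayed replica: compare against the sine shifted by the group delay
  delay <- k$group_delay_samples
  idx <- which(t > 2)
  expect_equal(out$algo_out[idx], x[idx - delay], tolerance = 0.02)
})

test_that("streaming controller_step equals the batch convolution", {
  k <- design_phase_shift_fir(10, 90, n_taps = 41)
  cc <- controller_config(k, gain = 1.5, output_max = 0.8)
  set.seed(21)
  x <- rnorm(300)
  batch <- controller_apply(x, cc)
  st <- controller_state(cc)
  stream_algo <- numeric(length(x))
  stream_int <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- controller_step(st, x[i], cc)
    stream_algo[i] <- r$algo_out
    stream_int[i] <- r$stim$intensity
    st <- r$state
  }
  expect_equal(stream_algo, batch$algo_out, tolerance = 1e-9)
  expect_equal(stream_int, batch$intensity, tolerance = 1e-9)
})

test_that("algorithm output is linear below saturation", {
  k <- design_phase_shift_fir(10, 45)
  cc <- controller_config(k, gain = 0.1, output_max = 1e6)
  set.seed(5)
  x <- rnorm(200, sd = 0.1)
  o1 <- controller_apply(x, cc)
  o2 <- controller_apply(2 * x, cc)
  expect_equal(o2$algo_out, 2 * o1$algo_out, tolerance = 1e-12)
  expect_equal(o2$intensity, 2 * o1$intensity, tolerance = 1e-12)
})

test_that("kernels survive a columnar text round trip", {
  k <- design_phase_shift_fir(10, 225, fs_hz = 500)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel(k, path)
  k2 <- read_kernel(path)
  expect_equal(k2$taps, k$taps, tolerance = 1e-12)
  expect_equal(k2$centre_freq_hz, 10)
  expect_equal(k2$phase_shift_deg, 225)
  expect_equal(k2$sample_rate_hz, 500)
  g <- glance(k2)
  expect_lt(g$phase_error_deg, 1)
  expect_equal(g$gain_at_f0, 1, tolerance = 1e-6)
})

test_that("negative intensities are rejected at the type level", {
  expect_error(stim_command(-0.1), class = "phasestim_config_error")
})
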