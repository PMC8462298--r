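# Analog front-end model: level shifter, Butterworth stages, ADC, chain.

test_that("level shifter maps the rated bipolar range onto the output rails", {
  expect_equal(level_shift(10), 3.3)
  expect_equal(level_shift(-10), 0)
  expect_equal(level_shift(0), 1.65)
  # saturation outside the rails
  expect_equal(level_shift(c(-50, 50)), c(0, 3.3))
  # custom spec
  sp <- level_shifter_spec(-1, 1, 0, 5)
  expect_equal(level_shift(c(-1, 0, 1), sp), c(0, 2.5, 5))
  expect_error(level_shifter_spec(1, -1), class = "phasestim_config_error")
})

test_that("level shifter is monotone and exactly affine inside the rails", {
  sp <- level_shifter_spec()
  x <- seq(-10, 10, length.out = 201)
  y <- level_shift(x, sp)
  expect_true(all(diff(y) >= 0))
  # affine: second differences vanish
  expect_lt(max(abs(diff(y, differences = 2))), 1e-12)
})

test_that("Butterworth designs hit the -3 dB point and are monotone in the passband sense", {
  aaf <- design_recursive_filter(recursive_filter_spec("lowpass", 2, 250, 1000))
  expect_equal(Mod(filter_response(aaf, 250)), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(Mod(filter_response(aaf, 0)), 1, tolerance = 1e-9)
  mags <- Mod(filter_response(aaf, c(100, 250, 499)))
  expect_true(mags[3] < mags[2] && mags[2] < mags[1])
  # high-pass: -3 dB at cutoff, full gain near Nyquist
  hp <- design_recursive_filter(recursive_filter_spec("highpass", 2, 1, 1000))
  expect_equal(Mod(filter_response(hp, 1)), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(Mod(filter_response(hp, 400)), 1, tolerance = 1e-3)
  expect_error(recursive_filter_spec("lowpass", 2, 500, 1000),
               class = "phasestim_config_error")
})

test_that("filter responses agree with the signal::freqz oracle", {
  for (spec in list(recursive_filter_spec("lowpass", 2, 250, 1000),
                    recursive_filter_spec("highpass", 2, 1, 1000),
                    recursive_filter_spec("lowpass", 1, 200, 1000))) {
    filt <- design_recursive_filter(spec)
    f <- c(0.5, 5, 50, 200, 350)
    w <- 2 * pi * f / spec$sample_rate_hz
    oracle <- signal::freqz(filt$b, filt$a, w)$h
    expect_equal(filter_response(filt, f), oracle, tolerance = 1e-10)
  }
})

test_that("all recursive-filter poles lie strictly inside the unit circle", {
  specs <- expand.grid(kind = c("lowpass", "highpass"), order = 1:4,
                       cutoff = c(0.5, 10, 200, 450),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    filt <- design_recursive_filter(
      recursive_filter_spec(specs$kind[i], specs$order[i], specs$cutoff[i], 1000))
    poles <- polyroot(rev(filt$a))
    expect_true(all(Mod(poles) < 1), label = sprintf(
      "stable poles for %s order %d at %g Hz",
      specs$kind[i], specs$order[i], specs$cutoff[i]))
  }
})

test_that("streaming filter_step reproduces batch apply_filter and signal::filter", {
  filt <- design_recursive_filter(recursive_filter_spec("lowpass", 2, 250, 1000))
  set.seed(7)
  x <- rnorm(300)
  batch <- apply_filter(x, filt)
  st <- filter_state(filt)
  stream <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- filter_step(st, x[i], filt)
    stream[i] <- r$output
    st <- r$state
  }
  expect_equal(stream, batch, tolerance = 1e-12)
  expect_equal(batch, as.numeric(signal::filter(filt$b, filt$a, x)),
               tolerance = 1e-12)
  expect_equal(apply_filter(numeric(10), filt), numeric(10))
})

test_that("a 10 Hz sine through the AAF settles to the predicted steady-state amplitude", {
  filt <- design_recursive_filter(recursive_filter_spec("lowpass", 2, 250, 1000))
  t <- seq(0, 5, by = 1e-3)
  y <- apply_filter(sin(2 * pi * 10 * t), filt)
  steady <- y[t > 1]
  expect_equal((max(steady) - min(steady)) / 2, Mod(filter_response(filt, 10)),
               tolerance = 0.01)
})

test_that("mid-rise quantization clamps at the end codes and bounds reconstruction error", {
  sp <- adc_spec(12, 0, 3.3)
  expect_identical(quantize(0, sp)$code, 0L)
  expect_identical(quantize(3.3, sp)$code, 4095L)
  expect_identical(quantize(-5, sp)$code, 0L)
  x <- seq(0, 3.3, length.out = 20001)
  q <- quantize(x, sp)
  step <- 3.3 / 2^12
  expect_lte(max(abs(q$volts - x)), step / 2 + 1e-12)
  # coarse ADC still monotone
  q3 <- quantize(seq(0, 3.3, length.out = 100), adc_spec(3, 0, 3.3))
  expect_true(all(diff(q3$code) >= 0))
})

test_that("chain_step matches the vectorised chain and respects stage enables", {
  cfg <- chain_config()
  set.seed(11)
  x <- rnorm(400, sd = 0.5)
  batch <- chain_apply(x, cfg)
  st <- chain_state(cfg)
  stream <- numeric(length(x))
  for (i in seq_along(x)) {
    r <- chain_step(st, x[i])
    stream[i] <- r$output
    st <- r$state
  }
  expect_equal(stream, batch, tolerance = 1e-9)
  # with every stage disabled the chain is the identity (times gain)
  passthru <- chain_config(enabled_stages = character(0), amp_gain = 2)
  expect_equal(chain_apply(x, passthru), 2 * x)
  expect_error(chain_config(enabled_stages = "warp_drive"),
               class = "phasestim_config_error")
})
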