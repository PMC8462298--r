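# Synthetic neural tissue: a stochastic damped harmonic oscillator near
# 10 Hz whose excitability is increased additively by (non-negative) light
# drive, plus a burst-train fixture generator for recording-path tests.

#' Plant configuration
#'
#' A linear stochastic resonator standing in for the neural tissue:
#' `x'' = -omega0^2 x - 2 zeta omega0 x' + k light + sigma xi(t)`,
#' integrated by semi-implicit (symplectic) Euler-Maruyama at the loop tick.
#' The recorded LFP is `x` plus white measurement noise. Light enters
#' additively on the acceleration (a depolarising drive) and is constrained
#' non-negative, so phase dependence of the closed loop arises from the
#' timing of rectified half-waves.
#'
#' The default noise level gives a stationary oscillation SD of ~0.5 V
#' (analytic stationary SD is `sigma / sqrt(4 zeta omega0^3)`), well inside
#' the +/-10 V front-end rails.
#'
#' @param natural_freq_hz Undamped natural frequency in Hz (default 10).
#' @param damping_ratio Dimensionless damping ratio in (0, 1); default 0.03
#'   (a narrow-band oscillation, spectral FWHM ~ 0.6 Hz at 10 Hz).
#' @param noise_sd Process-noise intensity sigma in V/s^(3/2); default 86,
#'   chosen for a ~0.5 V stationary SD at the default frequency and damping.
#' @param light_coupling Acceleration per light-unit in V/s^2 (default 1200).
#' @param dt_s Integration step, the loop tick (default 0.001 s).
#' @param measurement_noise_sd Recording noise SD in volts (default 0.01).
#' @param rng_seed Seed for open-loop simulation via [plant_simulate()].
#' @return An object of class `plant_config`.
#' @export
plant_config <- function(natural_freq_hz = 10, damping_ratio = 0.03,
                         noise_sd = 86, light_coupling = 1200,
                         dt_s = 0.001, measurement_noise_sd = 0.01,
                         rng_seed = 1) {
  check_number(natural_freq_hz, "natural_freq_hz", lower = 0, strict_lower = TRUE)
  check_number(damping_ratio, "damping_ratio", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(light_coupling, "light_coupling")
  check_number(dt_s, "dt_s", lower = 0, strict_lower = TRUE)
  check_number(measurement_noise_sd, "measurement_noise_sd", lower = 0)
  if (dt_s * natural_freq_hz > 0.05) {
    abort_config(
      "dt_s * natural_freq_hz = %g is too coarse for a stable oscillator step",
      dt_s * natural_freq_hz)
  }
  structure(
    list(natural_freq_hz = natural_freq_hz, damping_ratio = damping_ratio,
         noise_sd = noise_sd, light_coupling = light_coupling, dt_s = dt_s,
         measurement_noise_sd = measurement_noise_sd, rng_seed = rng_seed),
    class = "plant_config"
  )
}

#' Fresh plant state
#'
#' @param x Initial oscillation amplitude in volts.
#' @param v Initial velocity in volts/second.
#' @return An object of class `plant_state`.
#' @export
plant_state <- function(x = 0, v = 0) {
  check_number(x, "x")
  check_number(v, "v")
  structure(list(x = x, v = v), class = "plant_state")
}

#' Advance the plant by one tick
#'
#' One semi-implicit Euler-Maruyama step of the stochastic oscillator under
#' a non-negative light drive. Noise deviates are supplied explicitly (the
#' callers own the RNG) or drawn from the session RNG when omitted.
#'
#' @param state A [plant_state()].
#' @param light Light drive in light-units (must be >= 0).
#' @param config A [plant_config()].
#' @param xi,eta Standard-normal deviates for process and measurement noise;
#'   drawn from the current RNG when missing.
#' @return A list with `lfp_sample` (volts) and the updated `state`.
#' @export
plant_step <- function(state, light, config, xi = rnorm(1), eta = rnorm(1)) {
  if (!is_scalar_number(light) || light < 0) {
    rlang::abort("`light` must be a single non-negative number (an LED cannot emit negative light)",
                 class = "phasestim_contract_error")
  }
  omega0 <- 2 * pi * config$natural_freq_hz
  dt <- config$dt_s
  acc <- -omega0^2 * state$x - 2 * config$damping_ratio * omega0 * state$v +
    config$light_coupling * light
  v_new <- state$v + dt * acc + config$noise_sd * sqrt(dt) * xi
  x_new <- state$x + dt * v_new
  state$x <- x_new
  state$v <- v_new
  list(
    lfp_sample = x_new + config$measurement_noise_sd * eta,
    state = state
  )
}

#' Simulate the plant open loop
#'
#' Runs the plant for a fixed duration under a given light drive (scalar or
#' per-tick vector), with noise drawn reproducibly from the config seed.
#'
#' @param config A [plant_config()].
#' @param duration_s Simulation length in seconds.
#' @param light Light drive: a scalar or a vector of one value per tick.
#' @param state Initial [plant_state()].
#' @param seed Seed; defaults to `config$rng_seed`.
#' @return A tibble with `time_s`, `x`, `v` and `lfp` columns; sample rate
#'   `1/config$dt_s` stored in the `sample_rate_hz` attribute.
#' @export
plant_simulate <- function(config, duration_s, light = 0,
                           state = plant_state(), seed = config$rng_seed) {
  stopifnot(inherits(config, "plant_config"))
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  n <- round(duration_s / config$dt_s)
  light <- if (length(light) == 1L) rep(light, n) else light
  if (length(light) != n) abort_config("`light` must have length 1 or %d", n)
  if (any(light < 0)) {
    rlang::abort("`light` must be non-negative", class = "phasestim_contract_error")
  }
  noise <- with_seed(derive_seed(seed, "plant_process"), rnorm(n))
  mnoise <- with_seed(derive_seed(seed, "plant_measurement"), rnorm(n))
  res <- plant_run_core(
    n_ticks = as.integer(n),
    x0 = state$x, v0 = state$v,
    omega0 = 2 * pi * config$natural_freq_hz,
    zeta = config$damping_ratio, sigma = config$noise_sd,
    coupling = config$light_coupling, meas_sd = config$measurement_noise_sd,
    dt = config$dt_s, light = as.numeric(light), xi = noise, eta = mnoise
  )
  out <- tibble::tibble(
    time_s = (seq_len(n) - 1) * config$dt_s,
    x = res$x, v = res$v, lfp = res$lfp
  )
  attr(out, "sample_rate_hz") <- 1 / config$dt_s
  out
}

#' Stationary standard deviation of the open-loop plant
#'
#' Closed form for the linear stochastic oscillator:
#' `sd(x) = sigma / sqrt(4 zeta omega0^3)`.
#'
#' @param config A [plant_config()].
#' @return Stationary SD of `x` in volts.
#' @export
plant_stationary_sd <- function(config) {
  omega0 <- 2 * pi * config$natural_freq_hz
  config$noise_sd / sqrt(4 * config$damping_ratio * omega0^3)
}

#' Burst-train test signal
#'
#' Background white noise with randomly timed high-amplitude oscillatory
#' bursts (Hann-enveloped sine packets), emulating paroxysmal events for
#' recording-path tests. Burst onsets follow a Poisson process; the output
#' is deterministic given the seed.
#'
#' @param duration_s Signal length in seconds.
#' @param burst_rate_hz Mean burst rate in Hz (0 for pure background).
#' @param burst_freq_hz Oscillation frequency inside each burst.
#' @param fs Sample rate in Hz.
#' @param background_sd Background noise SD in volts.
#' @param burst_amplitude Peak burst amplitude in volts.
#' @param burst_duration_s Length of each burst envelope in seconds.
#' @param rng_seed Seed.
#' @return A tibble with `time_s` and `value`; attributes `sample_rate_hz`
#'   and `burst_onsets_s` (the drawn onset times).
#' @export
make_burst_signal <- function(duration_s, burst_rate_hz = 0.05,
                              burst_freq_hz = 10, fs = 500,
                              background_sd = 0.05, burst_amplitude = 0.5,
                              burst_duration_s = 2, rng_seed = 1) {
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(burst_rate_hz, "burst_rate_hz", lower = 0)
  n <- round(duration_s * fs)
  sig <- with_seed(derive_seed(rng_seed, "burst"), {
    x <- rnorm(n, sd = background_sd)
    n_bursts <- rpois(1, burst_rate_hz * duration_s)
    onsets <- sort(runif(n_bursts, 0, max(duration_s - burst_duration_s, 0)))
    m <- round(burst_duration_s * fs)
    env <- 0.5 - 0.5 * cos(2 * pi * seq_len(m) / (m + 1))
    for (t0 in onsets) {
      i0 <- round(t0 * fs) + 1L
      idx <- i0:min(i0 + m - 1L, n)
      tt <- (idx - i0) / fs
      x[idx] <- x[idx] +
        burst_amplitude * env[seq_along(idx)] * sin(2 * pi * burst_freq_hz * tt)
    }
    list(x = x, onsets = onsets)
  })
  out <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, value = sig$x)
  attr(out, "sample_rate_hz") <- fs
  attr(out, "burst_onsets_s") <- sig$onsets
  out
}
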