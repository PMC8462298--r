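# Shared fixtures: small configs and a brute-force DTFT oracle used to
# cross-check kernel responses independently of frequency_response().

dtft_oracle <- function(taps, f, fs) {
  k <- seq_along(taps) - 1
  sum(taps * complex(modulus = 1, argument = -2 * pi * f / fs * k))
}

# circular difference of two angles in degrees, in [0, 180]
angle_diff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

tiny_conditions <- function(gain = 8) {
  tibble::tibble(condition_id = 1:2, centre_freq_hz = 10,
                 phase_shift_deg = c(0, 180), gain = gain)
}

quick_loop_config <- function(seed = 1, gain = 8, on_s = 4, off_s = 4,
                              conditions = tiny_conditions(gain)) {
  loop_config(
    seed = seed,
    conditions = conditions,
    planner = planner_config(on_duration_s = on_s, off_duration_s = off_s)
  )
}
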