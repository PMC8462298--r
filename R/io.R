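# Configuration files, columnar signal files, fixtures and run manifests.

parse_header_lines <- function(lines) {
  hdr_lines <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in hdr_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

#' Default run configuration
#'
#' The fully defaulted nested configuration a YAML config file is validated
#' against and merged into: sections `loop`, `sigchain`, `controller`,
#' `scheduler`, `plant`, `analysis`, plus the global `seed` and `out_dir`.
#'
#' @return A nested list of defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1,
    out_dir = ".",
    loop = list(tick_period_s = 0.001, n_channels = 2, loop_delay_ticks = 1,
                duration_s = NULL),
    sigchain = list(
      amp_highpass_hz = 1, amp_highpass_order = 2,
      amp_lowpass_hz = 200, amp_lowpass_order = 1,
      amp_gain = 1,
      aaf_hz = 250, aaf_order = 2,
      level_in_min = -10, level_in_max = 10,
      level_out_min = 0, level_out_max = 3.3,
      adc_bits = 12,
      enabled_stages = c("amp_highpass", "amp_lowpass", "level_shifter",
                         "aaf", "adc")
    ),
    controller = list(n_taps = NULL, bandwidth_hz = 6, window = "hann",
                      output_max = 1),
    scheduler = list(on_duration_s = 10, off_duration_s = 10,
                     order = "pseudorandom", repetitions = 1,
                     centre_freq_hz = 10, phase_step_deg = 45, gain = 8),
    plant = list(natural_freq_hz = 10, damping_ratio = 0.03, noise_sd = 86,
                 light_coupling = 1200, measurement_noise_sd = 0.01),
    analysis = list(segment_s = 2, overlap_frac = 0.5, trim_s = 1,
                    f_min = 5, f_max = 20)
  )
}

merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort_config("unknown configuration key '%s'", full)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        abort_config("configuration key '%s' must be a section", full)
      }
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys (naming the offending
#' key), applies defaults for everything unstated, and assembles the typed
#' [loop_config()] (which enforces the numeric constraints: Nyquist bounds,
#' positive durations, valid rails).
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return A list of class `run_config` with the merged raw values
#'   (`$values`), the assembled `$loop` config and the `$analysis` section.
#' @export
load_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) abort_config("config file '%s' does not exist", path)
    yaml::read_yaml(path) %||% list()
  } else if (is.list(path)) {
    path
  } else {
    abort_config("`path` must be a file path or a named list")
  }
  values <- merge_config(default_run_config(), user)
  loop <- run_config_to_loop(values)
  structure(list(values = values, loop = loop, analysis = values$analysis),
            class = "run_config")
}

run_config_to_loop <- function(v) {
  tick <- v$loop$tick_period_s
  fs_chain <- 1 / tick
  sc <- v$sigchain
  chain <- chain_config(
    sample_rate_hz = fs_chain,
    amp_highpass = recursive_filter_spec("highpass", sc$amp_highpass_order,
                                         sc$amp_highpass_hz, fs_chain),
    amp_lowpass = recursive_filter_spec("lowpass", sc$amp_lowpass_order,
                                        sc$amp_lowpass_hz, fs_chain),
    amp_gain = sc$amp_gain,
    level_shifter = level_shifter_spec(sc$level_in_min, sc$level_in_max,
                                       sc$level_out_min, sc$level_out_max),
    aaf = recursive_filter_spec("lowpass", sc$aaf_order, sc$aaf_hz, fs_chain),
    adc = adc_spec(sc$adc_bits, sc$level_out_min, sc$level_out_max),
    enabled_stages = unlist(sc$enabled_stages)
  )
  sch <- v$scheduler
  loop_config(
    tick_period_s = tick,
    n_channels = v$loop$n_channels,
    loop_delay_ticks = v$loop$loop_delay_ticks,
    seed = v$seed,
    conditions = default_phase_grid(centre_freq_hz = sch$centre_freq_hz,
                                    gain = sch$gain,
                                    phase_step_deg = sch$phase_step_deg),
    planner = planner_config(on_duration_s = sch$on_duration_s,
                             off_duration_s = sch$off_duration_s,
                             order = sch$order,
                             repetitions = sch$repetitions,
                             rng_seed = v$seed),
    chain = chain,
    plant = plant_config(natural_freq_hz = v$plant$natural_freq_hz,
                         damping_ratio = v$plant$damping_ratio,
                         noise_sd = v$plant$noise_sd,
                         light_coupling = v$plant$light_coupling,
                         dt_s = tick,
                         measurement_noise_sd = v$plant$measurement_noise_sd,
                         rng_seed = v$seed),
    controller = list(n_taps = v$controller$n_taps,
                      bandwidth_hz = v$controller$bandwidth_hz,
                      window = v$controller$window,
                      output_max = v$controller$output_max)
  )
}

#' Write / read a columnar signal file
#'
#' Plain two-column text (`time_s`, `value`) with commented header lines
#' recording the sample rate, units and provenance. Round-trips values to at
#' least 12 significant digits; reading checks the time column is uniform at
#' the stated rate.
#'
#' @param path File path.
#' @param samples Numeric samples, or a tibble with `time_s` and `value`.
#' @param fs Sample rate in Hz (taken from the tibble attribute if present).
#' @param units Unit label stored in the header (default `"V"`).
#' @param meta Named list of extra header fields.
#' @return `write_signal` returns `path` invisibly; `read_signal` a tibble
#'   with `time_s`, `value` and attributes `sample_rate_hz`, `units`.
#' @export
write_signal <- function(path, samples, fs = NULL, units = "V", meta = list()) {
  if (is.data.frame(samples)) {
    fs <- fs %||% attr(samples, "sample_rate_hz")
    samples <- samples$value
  }
  if (is.null(fs)) abort_config("`fs` must be given (or carried by the tibble)")
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  hdr <- c(sprintf("# sample_rate_hz: %s", format_num(fs)),
           sprintf("# units: %s", units),
           vapply(names(meta), function(k) sprintf("# %s: %s", k, meta[[k]]),
                  character(1)),
           "# columns: time_s value")
  t <- (seq_along(samples) - 1) / fs
  writeLines(c(hdr, sprintf("%s\t%s", format_num(t), format_num(samples))), path)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) abort_data("signal file '%s' does not exist", path)
  lines <- readLines(path)
  hdr <- parse_header_lines(lines)
  if (is.null(hdr$sample_rate_hz)) {
    abort_data("signal file '%s' is missing the sample_rate_hz header", path)
  }
  fs <- as.numeric(hdr$sample_rate_hz)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("time_s", "value"))
  if (nrow(tab) > 1L) {
    dt <- diff(tab$time_s)
    if (max(abs(dt - 1 / fs)) > 1e-9 / fs + 1e-12) {
      abort_data("time column of '%s' is not uniform at %g Hz", path, fs)
    }
  }
  out <- tibble::as_tibble(tab)
  attr(out, "sample_rate_hz") <- fs
  attr(out, "units") <- hdr$units %||% "V"
  out
}

#' Generate a deterministic test signal
#'
#' Signal fixtures for bench-style tests: a sine (default 1 Vpp at 10 Hz,
#' reproducing the waveform-generator input of the bench stability check),
#' white noise, a burst train, or a linear chirp. Deterministic given the
#' seed.
#'
#' @param kind `"sine"`, `"white_noise"`, `"bursts"` or `"chirp"`.
#' @param duration_s Signal length in seconds.
#' @param fs Sample rate in Hz.
#' @param amplitude Sine/chirp amplitude in volts (default 0.5, i.e. 1 Vpp).
#' @param freq_hz Sine frequency in Hz (default 10).
#' @param sd White-noise SD in volts.
#' @param f_start_hz,f_end_hz Chirp frequency sweep in Hz.
#' @param burst_rate_hz Burst rate for `"bursts"`.
#' @param seed Seed.
#' @param path Optional path; when given the fixture is also written with
#'   [write_signal()].
#' @return A tibble (`time_s`, `value`) with a `sample_rate_hz` attribute.
#' @export
make_fixture <- function(kind = c("sine", "white_noise", "bursts", "chirp"),
                         duration_s = 60, fs = 1000, amplitude = 0.5,
                         freq_hz = 10, sd = 0.1, f_start_hz = 5,
                         f_end_hz = 15, burst_rate_hz = 0.05, seed = 1,
                         path = NULL) {
  kind <- match.arg(kind)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  out <- switch(kind,
    sine = tibble::tibble(time_s = t,
                          value = amplitude * sin(2 * pi * freq_hz * t)),
    white_noise = tibble::tibble(
      time_s = t,
      value = with_seed(derive_seed(seed, "fixture"), rnorm(n, sd = sd))
    ),
    bursts = {
      b <- make_burst_signal(duration_s, burst_rate_hz = burst_rate_hz,
                             fs = fs, rng_seed = seed)
      tibble::tibble(time_s = t, value = b$value)
    },
    chirp = {
      # linear sweep: instantaneous frequency f_start + (f_end-f_start) t/T
      phase <- 2 * pi * (f_start_hz * t +
                           (f_end_hz - f_start_hz) * t^2 / (2 * duration_s))
      tibble::tibble(time_s = t, value = amplitude * sin(phase))
    }
  )
  attr(out, "sample_rate_hz") <- fs
  if (!is.null(path)) {
    write_signal(path, out, fs = fs, meta = list(kind = kind, seed = seed))
  }
  out
}

#' Write a run manifest
#'
#' YAML echo of the full configuration, seeds and package version written
#' next to a run's outputs, sufficient to reproduce them bit-identically.
#'
#' @param path Output path.
#' @param config A `run_config` or `loop_config`.
#' @param outputs Character vector of files the run produced.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, outputs = character()) {
  cfg <- if (inherits(config, "run_config")) config$loop else config
  yaml::write_yaml(
    list(version = as.character(utils::packageVersion("phasestim")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = cfg$seed,
         outputs = as.list(outputs),
         config = serialize_loop_config(cfg)),
    path)
  invisible(path)
}
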