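# Discrete-time emulator of the firmware interrupt loop: at a fixed 1 ms
# tick it advances the plant, clocks the analog chain, runs the FIR
# controller on the control channel, applies the scheduler gate and logs a
# packet per tick. Also offline replay of recorded LFP files.

#' Effective per-channel sampling rate
#'
#' With one sample acquired per tick and channels read in an alternating
#' manner, each channel is sampled at `1 / (tick_period_s * n_channels)`.
#'
#' @param tick_period_s Loop tick period in seconds (default 0.001).
#' @param n_channels Number of alternating recording channels (default 2).
#' @return Rate in Hz.
#' @export
#' @examples
#' effective_channel_rate(0.001, 2)  # 500 Hz
effective_channel_rate <- function(tick_period_s = 0.001, n_channels = 2) {
  check_number(tick_period_s, "tick_period_s", lower = 0, strict_lower = TRUE)
  n_channels <- check_count(n_channels, "n_channels")
  1 / (tick_period_s * n_channels)
}

#' Loop configuration
#'
#' Ties together the sub-module configurations for a closed-loop session.
#' The controller runs at the effective rate of the control channel
#' (channel 0); with the defaults that is 500 Hz. The stimulation value
#' computed at tick `t` first reaches the plant at `t + loop_delay_ticks`
#' (the emulated loop latency, one full tick by default) and is held between
#' controller updates (zero-order hold).
#'
#' @param tick_period_s Loop tick period in seconds (default 0.001).
#' @param n_channels Number of alternating channels (default 2).
#' @param loop_delay_ticks Actuation latency in ticks (>= 1).
#' @param seed Session seed; all randomness derives from it via named
#'   substreams.
#' @param conditions Stimulation conditions, as from [default_phase_grid()].
#' @param planner A [planner_config()].
#' @param chain A [chain_config()] clocked at the tick rate.
#' @param plant A [plant_config()] with `dt_s = tick_period_s`.
#' @param controller A list of kernel-design and output parameters:
#'   `n_taps`, `bandwidth_hz`, `window`, `output_max`.
#' @return An object of class `loop_config`.
#' @export
loop_config <- function(tick_period_s = 0.001, n_channels = 2,
                        loop_delay_ticks = 1, seed = 1,
                        conditions = default_phase_grid(),
                        planner = planner_config(),
                        chain = chain_config(sample_rate_hz = 1 / tick_period_s),
                        plant = plant_config(dt_s = tick_period_s),
                        controller = list(n_taps = NULL, bandwidth_hz = 6,
                                          window = "hann", output_max = 1)) {
  check_number(tick_period_s, "tick_period_s", lower = 0, strict_lower = TRUE)
  n_channels <- check_count(n_channels, "n_channels")
  loop_delay_ticks <- check_count(loop_delay_ticks, "loop_delay_ticks")
  stopifnot(inherits(planner, "planner_config"),
            inherits(chain, "chain_config"),
            inherits(plant, "plant_config"))
  if (abs(chain$sample_rate_hz - 1 / tick_period_s) > 1e-9) {
    abort_config("chain sample rate (%g Hz) must equal the tick rate (%g Hz)",
                 chain$sample_rate_hz, 1 / tick_period_s)
  }
  if (abs(plant$dt_s - tick_period_s) > 1e-12) {
    abort_config("plant dt_s (%g s) must equal tick_period_s (%g s)",
                 plant$dt_s, tick_period_s)
  }
  fs_ctrl <- effective_channel_rate(tick_period_s, n_channels)
  bad_f0 <- conditions$centre_freq_hz >= fs_ctrl / 2
  if (any(bad_f0)) {
    abort_config("condition centre frequency %g Hz is at or above the controller Nyquist (%g Hz)",
                 conditions$centre_freq_hz[which(bad_f0)[1]], fs_ctrl / 2)
  }
  structure(
    list(tick_period_s = tick_period_s, n_channels = n_channels,
         loop_delay_ticks = loop_delay_ticks, seed = seed,
         conditions = tibble::as_tibble(conditions), planner = planner,
         chain = chain, plant = plant, controller = controller),
    class = "loop_config"
  )
}

# Designed per-condition kernels as an n_taps x n_conditions matrix.
condition_kernels <- function(config) {
  fs_ctrl <- effective_channel_rate(config$tick_period_s, config$n_channels)
  ctrl <- config$controller
  kernels <- lapply(seq_len(nrow(config$conditions)), function(i) {
    design_phase_shift_fir(
      f0_hz = config$conditions$centre_freq_hz[i],
      phase_deg = config$conditions$phase_shift_deg[i],
      fs_hz = fs_ctrl,
      n_taps = ctrl$n_taps,
      bandwidth_hz = ctrl$bandwidth_hz %||% 6,
      window = ctrl$window %||% "hann"
    )
  })
  n_taps <- vapply(kernels, function(k) k$n_taps, integer(1))
  if (length(unique(n_taps)) != 1L) {
    abort_config("all condition kernels must share one length")
  }
  list(kernels = kernels,
       taps = vapply(kernels, function(k) k$taps, numeric(n_taps[1])))
}

# Stage descriptors for the C++ chain: type 0 recursive, 1 gain,
# 2 level shifter, 3 ADC; recursive stages indexed into b/a lists.
chain_stage_plan <- function(chain) {
  filts <- list(
    amp_highpass = design_recursive_filter(chain$amp_highpass),
    amp_lowpass = design_recursive_filter(chain$amp_lowpass),
    aaf = design_recursive_filter(chain$aaf)
  )
  dc <- chain_dc_levels(chain, filts)
  type <- integer(0); idx <- integer(0); bs <- list(); as <- list()
  dcs <- numeric(0)
  add_rec <- function(nm) {
    f <- filts[[nm]]
    bs[[length(bs) + 1L]] <<- f$b
    as[[length(as) + 1L]] <<- f$a
    dcs <<- c(dcs, dc[[nm]])
    type <<- c(type, 0L); idx <<- c(idx, length(bs) - 1L)
  }
  if (chain_stage_enabled(chain, "amp_highpass")) add_rec("amp_highpass")
  if (chain_stage_enabled(chain, "amp_lowpass")) add_rec("amp_lowpass")
  type <- c(type, 1L); idx <- c(idx, 0L)  # amplifier gain
  if (chain_stage_enabled(chain, "level_shifter")) { type <- c(type, 2L); idx <- c(idx, 0L) }
  if (chain_stage_enabled(chain, "aaf")) add_rec("aaf")
  if (chain_stage_enabled(chain, "adc")) { type <- c(type, 3L); idx <- c(idx, 0L) }
  list(type = type, idx = idx, b = bs, a = as, dc = dcs)
}

#' Run a closed-loop session
#'
#' Emulates the firmware loop for the whole epoch plan (or a stated
#' duration): per tick the plant is advanced with the stimulation value
#' computed `loop_delay_ticks` earlier, the scheduled channel is sampled
#' through the analog chain, the FIR controller runs on the control channel,
#' the scheduler gate forces stimulation to zero in control epochs, and one
#' packet is logged. Deterministic given the session seed.
#'
#' @param config A [loop_config()].
#' @param duration_s Session length in seconds; defaults to the full plan.
#' @return An object of class `session_log`: a list with `header` (the
#'   config, seed, duration and package version -- sufficient to re-run the
#'   session bit-identically) and `packets`, a tibble with one row per tick
#'   (`tick`, `time_s`, `channel`, `raw_lfp`, `algo_out`, `stim_intensity`,
#'   `condition_id`, `epoch`).
#' @export
run_session <- function(config, duration_s = NULL) {
  stopifnot(inherits(config, "loop_config"))
  tick_hz <- 1 / config$tick_period_s
  plan <- build_plan(config$conditions, config$planner, tick_hz)
  duration_s <- duration_s %||% plan_duration_s(plan)
  check_number(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  n_ticks <- as.integer(round(duration_s * tick_hz))
  ticks <- plan_tick_index(plan, n_ticks)

  kern <- condition_kernels(config)
  stages <- chain_stage_plan(config$chain)
  xi <- with_seed(derive_seed(config$seed, "plant_process"), rnorm(n_ticks))
  eta <- with_seed(derive_seed(config$seed, "plant_measurement"), rnorm(n_ticks))

  res <- run_session_core(
    n_ticks = n_ticks, n_channels = config$n_channels,
    loop_delay = config$loop_delay_ticks, dt = config$tick_period_s,
    omega0 = 2 * pi * config$plant$natural_freq_hz,
    zeta = config$plant$damping_ratio, sigma = config$plant$noise_sd,
    coupling = config$plant$light_coupling,
    meas_sd = config$plant$measurement_noise_sd,
    xi = xi, eta = eta,
    stage_type = stages$type, stage_idx = stages$idx,
    chain_b = stages$b, chain_a = stages$a, stage_dc = stages$dc,
    chain_gain = config$chain$amp_gain,
    ls_in_min = config$chain$level_shifter$in_min,
    ls_in_max = config$chain$level_shifter$in_max,
    ls_out_min = config$chain$level_shifter$out_min,
    ls_out_max = config$chain$level_shifter$out_max,
    adc_bits = config$chain$adc$n_bits,
    adc_vmin = config$chain$adc$v_min, adc_vmax = config$chain$adc$v_max,
    dc_offset = chain_dc_offset(config$chain),
    taps = kern$taps, cond_gain = as.numeric(config$conditions$gain),
    output_max = config$controller$output_max %||% 1,
    cond_at_tick = ticks$condition
  )

  packets <- tibble::tibble(
    tick = seq_len(n_ticks) - 1L,
    time_s = (seq_len(n_ticks) - 1L) * config$tick_period_s,
    channel = res$channel,
    raw_lfp = res$raw,
    algo_out = res$algo_out,
    stim_intensity = res$stim,
    condition_id = ifelse(ticks$condition == 0L, NA_integer_,
                          config$conditions$condition_id[pmax(ticks$condition, 1L)]),
    epoch = ticks$epoch
  )
  log <- new_session_log(
    header = list(
      kind = "closed_loop",
      config = config, duration_s = duration_s,
      version = as.character(utils::packageVersion("phasestim")),
      fs_channel_hz = effective_channel_rate(config$tick_period_s,
                                             config$n_channels)
    ),
    packets = packets, plan = plan
  )
  # instrumentation for causality/cross-implementation audits (not part of
  # the persisted packet format)
  log$internals <- list(plant_x = res$plant_x)
  log
}

new_session_log <- function(header, packets, plan = NULL) {
  structure(list(header = header, packets = packets, plan = plan),
            class = "session_log")
}

#' Re-run a session from its own header
#'
#' Reproduces the packet stream bit-identically from the configuration and
#' seed stored in a session log.
#'
#' @param log A `session_log`.
#' @return A fresh `session_log`.
#' @export
rerun_session <- function(log) {
  stopifnot(inherits(log, "session_log"))
  if (identical(log$header$kind, "closed_loop")) {
    run_session(log$header$config, log$header$duration_s)
  } else {
    abort_data("only closed-loop session logs can be re-run from their header; replay logs are re-run with replay_session()")
  }
}

#' Replay recorded LFP through the chain and controller
#'
#' Open-loop mode: runs pre-recorded single-channel data through the analog
#' chain, the FIR controller and the scheduler gate (no plant), producing
#' the stimulation trace the hardware would have emitted. The file sample
#' rate must equal the controller rate implied by the config
#' (`effective_channel_rate`); replay is single-channel, so configs with
#' `n_channels = 1` match a file recorded at the tick rate.
#'
#' @param lfp A file path readable by [read_signal()], or a tibble with
#'   `time_s`/`value` columns and a `sample_rate_hz` attribute.
#' @param config A [loop_config()]; its chain is re-clocked at the file
#'   sample rate.
#' @return A `session_log` whose packets hold the recorded samples, the
#'   algorithm output and the stimulation trace.
#' @export
replay_session <- function(lfp, config) {
  stopifnot(inherits(config, "loop_config"))
  if (is.character(lfp)) lfp <- read_signal(lfp)
  fs <- attr(lfp, "sample_rate_hz")
  if (is.null(fs)) abort_data("input signal has no sample_rate_hz attribute")
  fs_ctrl <- effective_channel_rate(config$tick_period_s, config$n_channels)
  if (abs(fs - fs_ctrl) > 1e-9) {
    abort_data("signal sample rate (%g Hz) does not match the controller rate (%g Hz)",
               fs, fs_ctrl)
  }
  x <- lfp$value
  n <- length(x)

  # chain re-clocked at the controller rate (single-channel acquisition)
  chain <- replay_chain(config$chain, fs)
  recorded <- chain_apply(x, chain)
  ctrl_in <- recorded - chain_dc_offset(chain)

  plan <- build_plan(config$conditions, config$planner, tick_hz = fs)
  ticks <- plan_tick_index(plan, n)
  kern <- condition_kernels_at(config, fs)

  algo <- numeric(n)
  stim <- numeric(n)
  out_max <- config$controller$output_max %||% 1
  runs <- rle(ticks$condition)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in seq_along(runs$values)) {
    cond <- runs$values[j]
    if (cond == 0L) next
    idx <- starts[j]:ends[j]
    cc <- controller_config(kern$kernels[[cond]],
                            gain = config$conditions$gain[cond],
                            output_max = out_max)
    seg <- controller_apply(ctrl_in[idx], cc)  # history reset per epoch
    algo[idx] <- seg$algo_out
    stim[idx] <- seg$intensity
  }

  packets <- tibble::tibble(
    tick = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) / fs,
    channel = 0L,
    raw_lfp = recorded,
    algo_out = algo,
    stim_intensity = stim,
    condition_id = ifelse(ticks$condition == 0L, NA_integer_,
                          config$conditions$condition_id[pmax(ticks$condition, 1L)]),
    epoch = ticks$epoch
  )
  new_session_log(
    header = list(kind = "replay", config = config, duration_s = n / fs,
                  version = as.character(utils::packageVersion("phasestim")),
                  fs_channel_hz = fs),
    packets = packets, plan = plan
  )
}

replay_chain <- function(chain, fs) {
  redo <- function(spec) {
    recursive_filter_spec(spec$kind, spec$order, spec$cutoff_hz, fs)
  }
  enabled <- chain$enabled_stages
  # a low-pass corner at or above the new Nyquist is a no-op at this rate
  for (nm in c("aaf", "amp_lowpass")) {
    if (nm %in% enabled && chain[[nm]]$cutoff_hz >= fs / 2) {
      enabled <- setdiff(enabled, nm)
    }
  }
  placeholder <- recursive_filter_spec("lowpass", 1, fs / 4, fs)
  chain_config(
    sample_rate_hz = fs,
    amp_highpass = if ("amp_highpass" %in% enabled) redo(chain$amp_highpass) else placeholder,
    amp_lowpass = if ("amp_lowpass" %in% enabled) redo(chain$amp_lowpass) else placeholder,
    amp_gain = chain$amp_gain,
    level_shifter = chain$level_shifter,
    aaf = if ("aaf" %in% enabled) redo(chain$aaf) else placeholder,
    adc = chain$adc,
    enabled_stages = enabled
  )
}

condition_kernels_at <- function(config, fs) {
  cfg <- config
  cfg$tick_period_s <- 1 / (fs * config$n_channels)
  condition_kernels(cfg)
}

#' @export
print.session_log <- function(x, ...) {
  h <- x$header
  cat(sprintf("<session_log> %s | %g s, %d packets @ %g Hz tick, %d channel(s)\n",
              h$kind, h$duration_s, nrow(x$packets),
              1 / h$config$tick_period_s, h$config$n_channels))
  invisible(x)
}

#' @export
tidy.session_log <- function(x, ...) x$packets

#' @export
glance.session_log <- function(x, ...) {
  p <- x$packets
  tibble::tibble(
    kind = x$header$kind,
    duration_s = x$header$duration_s,
    n_packets = nrow(p),
    n_channels = x$header$config$n_channels,
    fs_channel_hz = x$header$fs_channel_hz,
    n_epochs = length(unique(stats::na.omit(p$epoch))),
    stim_duty = mean(p$stim_intensity > 0),
    mean_stim = mean(p$stim_intensity)
  )
}

# Control-channel series of a session log (the channel the controller
# reads), with its sample rate attached.
control_channel <- function(log) {
  stopifnot(inherits(log, "session_log"))
  p <- log$packets[log$packets$channel == 0L, ]
  attr(p, "sample_rate_hz") <- log$header$fs_channel_hz
  p
}

#' Write / read a session log as self-describing text
#'
#' A commented YAML header block (configs, seed, version) followed by the
#' packet table in tab-separated columns. The header is sufficient to re-run
#' a closed-loop session bit-identically.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @return `write_session_log` returns `path` invisibly; `read_session_log`
#'   the reconstructed `session_log`.
#' @export
write_session_log <- function(log, path) {
  stopifnot(inherits(log, "session_log"))
  hdr_yaml <- yaml::as.yaml(serialize_header(log$header))
  hdr <- paste0("#| ", strsplit(hdr_yaml, "\n", fixed = TRUE)[[1]])
  p <- log$packets
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(p), collapse = "\t"), con)
  body <- sprintf("%d\t%s\t%d\t%s\t%s\t%s\t%s\t%s",
                  p$tick, format_num(p$time_s), p$channel,
                  format_num(p$raw_lfp), format_num(p$algo_out),
                  format_num(p$stim_intensity),
                  ifelse(is.na(p$condition_id), "CONTROL", p$condition_id),
                  ifelse(is.na(p$epoch), "NA", p$epoch))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#|")
  hdr <- yaml::yaml.load(paste(sub("^#\\| ?", "", lines[is_hdr]), collapse = "\n"))
  tab <- utils::read.table(text = lines[!is_hdr], header = TRUE, sep = "\t",
                           na.strings = "NA",
                           colClasses = c("integer", "numeric", "integer",
                                          "numeric", "numeric", "numeric",
                                          "character", "integer"))
  tab$condition_id <- suppressWarnings(
    ifelse(tab$condition_id == "CONTROL", NA_integer_,
           as.integer(tab$condition_id)))
  header <- deserialize_header(hdr)
  log <- new_session_log(header = header, packets = tibble::as_tibble(tab))
  if (identical(header$kind, "closed_loop") && !is.null(header$config)) {
    log$plan <- build_plan(header$config$conditions, header$config$planner,
                           1 / header$config$tick_period_s)
  }
  log
}

serialize_header <- function(header) {
  cfg <- header$config
  list(
    kind = header$kind,
    duration_s = header$duration_s,
    version = header$version,
    fs_channel_hz = header$fs_channel_hz,
    config = serialize_loop_config(cfg)
  )
}

serialize_loop_config <- function(cfg) {
  list(
    tick_period_s = cfg$tick_period_s,
    n_channels = cfg$n_channels,
    loop_delay_ticks = cfg$loop_delay_ticks,
    seed = cfg$seed,
    conditions = lapply(seq_len(nrow(cfg$conditions)), function(i) {
      as.list(cfg$conditions[i, ])
    }),
    planner = unclass(cfg$planner),
    chain = list(
      sample_rate_hz = cfg$chain$sample_rate_hz,
      amp_highpass = unclass(cfg$chain$amp_highpass),
      amp_lowpass = unclass(cfg$chain$amp_lowpass),
      amp_gain = cfg$chain$amp_gain,
      level_shifter = unclass(cfg$chain$level_shifter),
      aaf = unclass(cfg$chain$aaf),
      adc = unclass(cfg$chain$adc),
      enabled_stages = as.list(cfg$chain$enabled_stages)
    ),
    plant = unclass(cfg$plant),
    controller = cfg$controller
  )
}

deserialize_header <- function(hdr) {
  cfg <- hdr$config
  rfs <- function(x) recursive_filter_spec(x$kind, x$order, x$cutoff_hz,
                                           x$sample_rate_hz)
  conditions <- dplyr::bind_rows(lapply(cfg$conditions, tibble::as_tibble))
  config <- loop_config(
    tick_period_s = cfg$tick_period_s,
    n_channels = cfg$n_channels,
    loop_delay_ticks = cfg$loop_delay_ticks,
    seed = cfg$seed,
    conditions = conditions,
    planner = do.call(planner_config, cfg$planner),
    chain = chain_config(
      sample_rate_hz = cfg$chain$sample_rate_hz,
      amp_highpass = rfs(cfg$chain$amp_highpass),
      amp_lowpass = rfs(cfg$chain$amp_lowpass),
      amp_gain = cfg$chain$amp_gain,
      level_shifter = do.call(level_shifter_spec, cfg$chain$level_shifter),
      aaf = rfs(cfg$chain$aaf),
      adc = do.call(adc_spec, cfg$chain$adc),
      enabled_stages = unlist(cfg$chain$enabled_stages)
    ),
    plant = do.call(plant_config, cfg$plant),
    controller = cfg$controller
  )
  list(kind = hdr$kind, config = config, duration_s = hdr$duration_s,
       version = hdr$version, fs_channel_hz = hdr$fs_channel_hz)
}
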