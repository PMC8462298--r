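# Experiment planner: stimulation conditions, epoch plans (ON epochs
# interleaved with no-stimulation control epochs), sequential or seeded
# pseudorandom ordering, and per-tick condition lookup.

#' Default 8-condition phase grid
#'
#' Stimulation conditions sweeping the commanded phase shift from 0 to 315
#' degrees in 45-degree steps at a shared centre frequency and gain.
#'
#' @param centre_freq_hz Shared FIR centre frequency in Hz (default 10).
#' @param gain Shared LFP-to-light gain (default 8).
#' @param phase_step_deg Phase increment in degrees (default 45).
#' @return A tibble of conditions (`condition_id`, `centre_freq_hz`,
#'   `phase_shift_deg`, `gain`).
#' @export
#' @examples
#' default_phase_grid()
default_phase_grid <- function(centre_freq_hz = 10, gain = 8,
                               phase_step_deg = 45) {
  check_number(phase_step_deg, "phase_step_deg", lower = 0, strict_lower = TRUE)
  phases <- seq(0, 360 - phase_step_deg, by = phase_step_deg)
  tibble::tibble(
    condition_id = seq_along(phases),
    centre_freq_hz = centre_freq_hz,
    phase_shift_deg = phases,
    gain = gain
  )
}

#' Planner configuration
#'
#' @param on_duration_s Duration of each stimulation epoch in seconds (> 0).
#' @param off_duration_s Duration of the control (no-stimulation) period
#'   following each stimulation epoch, in seconds (>= 0).
#' @param order `"sequential"` or `"pseudorandom"` (a seeded permutation per
#'   repetition block).
#' @param repetitions Number of times each condition is delivered (>= 1).
#' @param rng_seed Seed for the pseudorandom ordering.
#' @return An object of class `planner_config`.
#' @export
planner_config <- function(on_duration_s = 10, off_duration_s = 10,
                           order = c("sequential", "pseudorandom"),
                           repetitions = 1, rng_seed = 1) {
  order <- match.arg(order)
  check_number(on_duration_s, "on_duration_s", lower = 0, strict_lower = TRUE)
  check_number(off_duration_s, "off_duration_s", lower = 0)
  repetitions <- check_count(repetitions, "repetitions")
  structure(
    list(on_duration_s = on_duration_s, off_duration_s = off_duration_s,
         order = order, repetitions = repetitions, rng_seed = rng_seed),
    class = "planner_config"
  )
}

#' Build an epoch plan
#'
#' Expands a condition list into a contiguous, non-overlapping sequence of
#' timed epochs. Each stimulation epoch is immediately followed by its
#' control epoch (when `off_duration_s > 0`), so controls are interspersed
#' with stimulation. With `order = "pseudorandom"` the condition order is a
#' seeded permutation drawn independently within each repetition block;
#' plans are bit-identical across runs and platforms for a fixed seed.
#'
#' @param conditions A tibble of conditions as from [default_phase_grid()].
#' @param config A [planner_config()].
#' @param tick_hz Loop tick rate in Hz used to convert seconds to ticks.
#' @return A tibble of class `epoch_plan` with one row per epoch: `epoch`,
#'   `start_tick`, `end_tick` (inclusive), `start_s`, `end_s`,
#'   `condition_id` (`NA` for control), `is_control`, `ref_condition_id`
#'   (the preceding stimulation condition, for paired analysis), plus the
#'   condition parameters.
#' @export
#' @examples
#' plan <- build_plan(default_phase_grid(), planner_config(10, 10), 1000)
#' condition_at(plan, 0)
build_plan <- function(conditions, config, tick_hz = 1000) {
  if (!inherits(config, "planner_config")) {
    abort_config("`config` must be a planner_config")
  }
  check_number(tick_hz, "tick_hz", lower = 0, strict_lower = TRUE)
  if (!is.data.frame(conditions) || nrow(conditions) == 0L) {
    abort_config("`conditions` must be a non-empty data frame")
  }
  req <- c("condition_id", "centre_freq_hz", "phase_shift_deg", "gain")
  missing_cols <- setdiff(req, names(conditions))
  if (length(missing_cols)) {
    abort_config("`conditions` is missing column(s): %s", toString(missing_cols))
  }
  if (anyDuplicated(conditions$condition_id)) {
    abort_config("condition_id values must be unique")
  }
  if (any(conditions$phase_shift_deg < 0 | conditions$phase_shift_deg >= 360)) {
    abort_config("phase_shift_deg must lie in [0, 360)")
  }

  n_cond <- nrow(conditions)
  ordering <- unlist(lapply(seq_len(config$repetitions), function(block) {
    if (config$order == "sequential") {
      seq_len(n_cond)
    } else {
      with_seed(derive_seed(config$rng_seed + (block - 1L) * 7919, "plan"),
                sample.int(n_cond))
    }
  }))

  on_ticks <- round(config$on_duration_s * tick_hz)
  off_ticks <- round(config$off_duration_s * tick_hz)
  rows <- list()
  tick <- 0
  epoch <- 0L
  for (i in ordering) {
    cond <- conditions[i, ]
    epoch <- epoch + 1L
    rows[[length(rows) + 1L]] <- tibble::tibble(
      epoch = epoch, start_tick = tick, end_tick = tick + on_ticks - 1,
      condition_id = cond$condition_id, is_control = FALSE,
      ref_condition_id = cond$condition_id,
      centre_freq_hz = cond$centre_freq_hz,
      phase_shift_deg = cond$phase_shift_deg, gain = cond$gain
    )
    tick <- tick + on_ticks
    if (off_ticks > 0) {
      epoch <- epoch + 1L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        epoch = epoch, start_tick = tick, end_tick = tick + off_ticks - 1,
        condition_id = NA_integer_, is_control = TRUE,
        ref_condition_id = cond$condition_id,
        centre_freq_hz = NA_real_, phase_shift_deg = NA_real_, gain = NA_real_
      )
      tick <- tick + off_ticks
    }
  }
  plan <- dplyr::bind_rows(rows)
  plan <- dplyr::mutate(plan,
                        start_s = .data$start_tick / tick_hz,
                        end_s = (.data$end_tick + 1) / tick_hz,
                        .after = "end_tick")
  attr(plan, "tick_hz") <- tick_hz
  attr(plan, "conditions") <- conditions
  attr(plan, "planner_config") <- config
  class(plan) <- c("epoch_plan", class(plan))
  plan
}

#' Look up the active condition at a tick
#'
#' @param plan An [build_plan()] epoch plan.
#' @param tick Tick index (0-based); must lie within the plan.
#' @return A one-row tibble: the epoch row for that tick (`is_control = TRUE`
#'   marks a no-stimulation control period).
#' @export
condition_at <- function(plan, tick) {
  stopifnot(inherits(plan, "epoch_plan"))
  if (length(tick) != 1L || tick < 0 || tick > plan$end_tick[nrow(plan)]) {
    abort_data("tick %s is outside the plan (0..%d)",
               format(tick), plan$end_tick[nrow(plan)])
  }
  i <- findInterval(tick, plan$start_tick)
  tibble::as_tibble(plan[i, ])
}

#' Total plan duration in seconds
#' @param plan An epoch plan.
#' @return Duration in seconds.
#' @export
plan_duration_s <- function(plan) {
  stopifnot(inherits(plan, "epoch_plan"))
  (plan$end_tick[nrow(plan)] + 1) / attr(plan, "tick_hz")
}

# Per-tick expansion used by the loop engine: integer vector of length
# n_ticks with 0 = control / beyond plan, otherwise the row index of the
# condition in attr(plan, "conditions"); plus epoch index per tick.
plan_tick_index <- function(plan, n_ticks) {
  conds <- attr(plan, "conditions")
  cond_row <- match(plan$condition_id, conds$condition_id)
  cond_row[plan$is_control] <- 0L
  len <- plan$end_tick - plan$start_tick + 1
  cond_at_tick <- rep(cond_row, times = len)
  epoch_at_tick <- rep(plan$epoch, times = len)
  if (length(cond_at_tick) < n_ticks) {
    pad <- n_ticks - length(cond_at_tick)
    cond_at_tick <- c(cond_at_tick, rep(0L, pad))
    epoch_at_tick <- c(epoch_at_tick, rep(NA_integer_, pad))
  }
  list(condition = as.integer(cond_at_tick[seq_len(n_ticks)]),
       epoch = as.integer(epoch_at_tick[seq_len(n_ticks)]))
}

#' Write / read an epoch plan as columnar text
#'
#' @param plan An epoch plan.
#' @param path File path.
#' @return `write_plan` returns `path` invisibly; `read_plan` the tibble.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "epoch_plan"))
  hdr <- sprintf("# tick_hz: %s", format_num(attr(plan, "tick_hz")))
  df <- as.data.frame(plan)
  df$condition_id <- ifelse(plan$is_control, "CONTROL", plan$condition_id)
  body <- c(paste(names(df), collapse = "\t"),
            do.call(paste, c(lapply(df, as.character), sep = "\t")))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  hdr <- parse_header_lines(lines)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  tab$is_control <- tab$condition_id == "CONTROL"
  tab$condition_id <- suppressWarnings(as.integer(tab$condition_id))
  out <- tibble::as_tibble(tab)
  attr(out, "tick_hz") <- as.numeric(hdr$tick_hz %||% NA_real_)
  class(out) <- c("epoch_plan", class(out))
  out
}

#' @export
glance.epoch_plan <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x),
    n_stim_epochs = sum(!x$is_control),
    n_control_epochs = sum(x$is_control),
    n_conditions = dplyr::n_distinct(x$condition_id[!x$is_control]),
    duration_s = plan_duration_s(x),
    tick_hz = attr(x, "tick_hz")
  )
}
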