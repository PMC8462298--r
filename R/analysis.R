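# Spectral analysis: Welch power spectra, dominant-frequency detection
# (the bench stability check), per-condition epoch slicing and the
# frequency x phase modulation map relative to no-stimulation epochs.

#' Welch power spectral density estimate
#'
#' Averaged windowed periodogram over (optionally overlapping) segments,
#' scaled so the integrated one-sided PSD equals the mean square of the
#' windowed signal (a discrete Parseval identity).
#'
#' @param signal Numeric samples.
#' @param fs Sample rate in Hz.
#' @param segment_len Segment length in samples (default 2 s worth).
#' @param overlap_frac Fractional overlap between segments in `[0, 1)`.
#' @param window `"hann"` or `"rect"`.
#' @return A tibble of class `spectral_estimate` with columns `freq_hz` and
#'   `power` (units^2 per Hz); attributes `fs`, `n_segments`, `segment_len`,
#'   `overlap_frac`, `window`.
#' @export
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 60, by = 1/500))
#' est <- estimate_psd(x, fs = 500)
#' dominant_frequency(est, 1, 50)
estimate_psd <- function(signal, fs, segment_len = round(2 * fs),
                         overlap_frac = 0.5, window = c("hann", "rect")) {
  window <- match.arg(window)
  check_number(fs, "fs", lower = 0, strict_lower = TRUE)
  segment_len <- check_count(segment_len, "segment_len", lower = 2L)
  check_number(overlap_frac, "overlap_frac", lower = 0, upper = 1,
               strict_upper = TRUE)
  n <- length(signal)
  if (n < segment_len) {
    abort_data("signal (%d samples) is shorter than one segment (%d samples)",
               n, segment_len)
  }
  step <- max(1L, round(segment_len * (1 - overlap_frac)))
  starts <- seq(1L, n - segment_len + 1L, by = step)
  w <- switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(segment_len) - 1) / (segment_len - 1)),
    rect = rep(1, segment_len)
  )
  u <- sum(w^2)
  n_freq <- floor(segment_len / 2) + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- signal[s:(s + segment_len - 1L)] * w
    p <- Mod(fft(seg))^2 / (fs * u)
    acc <- acc + p[seq_len(n_freq)]
  }
  pxx <- acc / length(starts)
  # one-sided: fold negative frequencies (all bins except DC and Nyquist)
  if (segment_len %% 2L == 0L) {
    pxx[2:(n_freq - 1L)] <- 2 * pxx[2:(n_freq - 1L)]
  } else {
    pxx[2:n_freq] <- 2 * pxx[2:n_freq]
  }
  out <- tibble::tibble(
    freq_hz = (seq_len(n_freq) - 1) * fs / segment_len,
    power = pxx
  )
  attr(out, "fs") <- fs
  attr(out, "n_segments") <- length(starts)
  attr(out, "segment_len") <- segment_len
  attr(out, "overlap_frac") <- overlap_frac
  attr(out, "window") <- window
  class(out) <- c("spectral_estimate", class(out))
  out
}

#' Dominant frequency within a band
#'
#' Frequency of maximum estimated power in `[f_min, f_max]`; exact ties are
#' broken toward the lower frequency.
#'
#' @param est A [estimate_psd()] result.
#' @param f_min,f_max Band edges in Hz (inclusive).
#' @return The dominant frequency in Hz.
#' @export
dominant_frequency <- function(est, f_min, f_max) {
  stopifnot(inherits(est, "spectral_estimate"))
  check_number(f_min, "f_min")
  check_number(f_max, "f_max")
  sel <- est$freq_hz >= f_min & est$freq_hz <= f_max
  if (!any(sel)) {
    abort_data("band [%g, %g] Hz contains no frequency bins", f_min, f_max)
  }
  band <- est[sel, ]
  band$freq_hz[which.max(band$power)]
}

#' Per-condition sample slices of a session log
#'
#' Splits the control-channel series into contiguous per-epoch slices,
#' discarding the first `trim_s` seconds of every epoch to remove filter and
#' loop transients.
#'
#' @param log A `session_log`.
#' @param trim_s Seconds trimmed from each epoch head (default 1).
#' @return A tibble with one row per epoch: `epoch`, `condition_id`,
#'   `is_control`, `phase_shift_deg`, `n_samples` and `idx` (a list column
#'   of integer indices into the control-channel series, post-trim).
#'   The control-channel series itself is attached as attribute `series`
#'   with its sample rate in `fs`.
#' @export
epoch_slices <- function(log, trim_s = 1) {
  stopifnot(inherits(log, "session_log"))
  check_number(trim_s, "trim_s", lower = 0)
  ctrl <- control_channel(log)
  fs <- attr(ctrl, "sample_rate_hz")
  if (all(is.na(ctrl$epoch))) abort_data("session log has no epochs")
  conds <- log$header$config$conditions
  trim_n <- round(trim_s * fs)
  idx_by_epoch <- split(seq_len(nrow(ctrl)), ctrl$epoch)
  rows <- purrr::map(names(idx_by_epoch), function(ep) {
    idx <- idx_by_epoch[[ep]]
    if (trim_n > 0) {
      idx <- if (length(idx) > trim_n) idx[-seq_len(trim_n)] else integer(0)
    }
    first <- idx_by_epoch[[ep]][1]
    cid <- ctrl$condition_id[first]
    tibble::tibble(
      epoch = as.integer(ep),
      condition_id = cid,
      is_control = is.na(cid),
      phase_shift_deg = if (is.na(cid)) NA_real_ else {
        conds$phase_shift_deg[match(cid, conds$condition_id)]
      },
      n_samples = length(idx),
      idx = list(idx)
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(rows), .data$epoch)
  attr(out, "series") <- ctrl$raw_lfp
  attr(out, "fs") <- fs
  attr(out, "trim_s") <- trim_s
  out
}

#' Frequency x phase modulation map
#'
#' For each stimulation condition, estimates a Welch PSD per epoch (never
#' averaging across epoch discontinuities), averages PSDs within condition,
#' and expresses the result in dB relative to the pooled no-stimulation
#' control spectrum: `M(f, phi) = 10 log10(P_phi(f) / P_control(f))`. The
#' phase axis can be tiled over two cycles (0-720 degrees) to reveal the
#' enhancement/suppression pattern more clearly.
#'
#' @param log A `session_log` with at least one epoch per condition and at
#'   least one control epoch.
#' @param f_min,f_max Frequency band retained in the map (Hz).
#' @param segment_s Welch segment length in seconds (default 2, i.e. 0.5 Hz
#'   resolution).
#' @param overlap_frac Segment overlap (default 0.5).
#' @param trim_s Epoch head-trim in seconds (default 1).
#' @param two_cycles Tile the phase axis over 0-720 degrees (default TRUE).
#' @return A tibble of class `modulation_map` with columns `freq_hz`,
#'   `phase_deg`, `condition_id`, `modulation_db`.
#' @export
modulation_map <- function(log, f_min = 0, f_max = Inf, segment_s = 2,
                           overlap_frac = 0.5, trim_s = 1,
                           two_cycles = TRUE) {
  slices <- epoch_slices(log, trim_s = trim_s)
  series <- attr(slices, "series")
  fs <- attr(slices, "fs")
  seg_len <- round(segment_s * fs)

  usable <- slices[slices$n_samples >= seg_len, ]
  if (!any(usable$is_control)) {
    abort_data("session log contains no usable control (no-stimulation) epochs")
  }
  if (!any(!usable$is_control)) {
    abort_data("session log contains no usable stimulation epochs")
  }

  psd_of <- function(idx) {
    estimate_psd(series[idx], fs, segment_len = seg_len,
                 overlap_frac = overlap_frac)
  }
  mean_psd <- function(rows) {
    ests <- purrr::map(rows$idx, psd_of)
    power <- Reduce(`+`, purrr::map(ests, "power")) / length(ests)
    tibble::tibble(freq_hz = ests[[1]]$freq_hz, power = power)
  }

  p_control <- mean_psd(usable[usable$is_control, ])
  stim <- usable[!usable$is_control, ]
  conds <- unique(stim[, c("condition_id", "phase_shift_deg")])
  conds <- dplyr::arrange(conds, .data$phase_shift_deg)

  map <- purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    rows <- stim[stim$condition_id == conds$condition_id[i], ]
    p <- mean_psd(rows)
    tibble::tibble(
      freq_hz = p$freq_hz,
      phase_deg = conds$phase_shift_deg[i],
      condition_id = conds$condition_id[i],
      modulation_db = 10 * log10(p$power / p_control$power)
    )
  })
  map <- map[map$freq_hz >= f_min & map$freq_hz <= f_max &
               is.finite(map$modulation_db), ]
  if (two_cycles) {
    map <- dplyr::bind_rows(
      map,
      dplyr::mutate(map, phase_deg = .data$phase_deg + 360)
    )
  }
  attr(map, "fs") <- fs
  attr(map, "segment_s") <- segment_s
  attr(map, "trim_s") <- trim_s
  attr(map, "two_cycles") <- two_cycles
  attr(map, "control_power") <- p_control
  class(map) <- c("modulation_map", class(map))
  map
}

#' Modulation extrema within a band
#'
#' Locates the strongest enhancement and the strongest suppression of the
#' modulation map in a frequency band, together with their phase conditions
#' and the circular separation between those phases. With
#' `statistic = "pointwise"` (default) the extrema are taken over individual
#' (frequency, phase) cells -- the deepest red and blue of the map; with
#' `statistic = "band_mean"` the map is first averaged over the band per
#' phase condition.
#'
#' @param map A [modulation_map()].
#' @param f_min,f_max Band edges in Hz.
#' @param statistic `"pointwise"` or `"band_mean"`.
#' @return A one-row tibble: `max_db`, `max_phase_deg`, `min_db`,
#'   `min_phase_deg`, `phase_separation_deg` (circular, in `[0, 180]`),
#'   `peak_freq_hz` (frequency of the maximal enhancement).
#' @export
modulation_extrema <- function(map, f_min = 8, f_max = 12,
                               statistic = c("pointwise", "band_mean")) {
  stopifnot(inherits(map, "modulation_map"))
  statistic <- match.arg(statistic)
  one <- map[map$phase_deg < 360, ]
  band <- one[one$freq_hz >= f_min & one$freq_hz <= f_max, ]
  if (nrow(band) == 0L) abort_data("band [%g, %g] Hz is empty", f_min, f_max)
  if (statistic == "pointwise") {
    i_max <- which.max(band$modulation_db)
    i_min <- which.min(band$modulation_db)
    max_db <- band$modulation_db[i_max]
    min_db <- band$modulation_db[i_min]
    max_phase <- band$phase_deg[i_max]
    min_phase <- band$phase_deg[i_min]
    peak_freq <- band$freq_hz[i_max]
  } else {
    by_phase <- dplyr::summarise(
      dplyr::group_by(band, .data$phase_deg),
      band_db = mean(.data$modulation_db), .groups = "drop")
    i_max <- which.max(by_phase$band_db)
    i_min <- which.min(by_phase$band_db)
    max_db <- by_phase$band_db[i_max]
    min_db <- by_phase$band_db[i_min]
    max_phase <- by_phase$phase_deg[i_max]
    min_phase <- by_phase$phase_deg[i_min]
    best_phase <- band[band$phase_deg == max_phase, ]
    peak_freq <- best_phase$freq_hz[which.max(best_phase$modulation_db)]
  }
  sep <- abs(max_phase - min_phase) %% 360
  sep <- min(sep, 360 - sep)
  tibble::tibble(
    max_db = max_db, max_phase_deg = max_phase,
    min_db = min_db, min_phase_deg = min_phase,
    phase_separation_deg = sep, peak_freq_hz = peak_freq
  )
}

#' @export
glance.modulation_map <- function(x, f_min = 0, f_max = Inf, ...) {
  modulation_extrema(x, f_min = max(f_min, min(x$freq_hz)),
                     f_max = min(f_max, max(x$freq_hz)))
}

#' @export
tidy.modulation_map <- function(x, ...) {
  tibble::as_tibble(x[, c("freq_hz", "phase_deg", "condition_id", "modulation_db")])
}

#' Write a modulation map as columnar text
#'
#' @param map A `modulation_map`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_modulation_map <- function(map, path) {
  stopifnot(inherits(map, "modulation_map"))
  hdr <- c("# columns: freq_hz phase_deg condition_id modulation_db")
  rows <- sprintf("%s\t%s\t%d\t%s", format_num(map$freq_hz),
                  format_num(map$phase_deg), map$condition_id,
                  format_num(map$modulation_db))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Heat-map of a modulation map
#'
#' Enhancement in red, suppression in blue, on a phase x frequency grid
#' (two phase cycles when tiled).
#'
#' @param object A `modulation_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.modulation_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$phase_deg, y = .data$freq_hz,
                               fill = .data$modulation_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue3", mid = "white",
                                  high = "red3", name = "dB") +
    ggplot2::labs(x = "commanded phase shift (deg)", y = "frequency (Hz)",
                  title = "Power modulation relative to no-stimulation epochs")
}

#' Plot a spectral estimate
#'
#' @param object A `spectral_estimate`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectral_estimate <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$freq_hz, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power (units²/Hz)",
                  title = sprintf("Welch PSD (%d segments)",
                                  attr(object, "n_segments")))
}

#' Bench stability check, emulated end to end
#'
#' Feeds a 1 Vpp, 10 Hz sine fixture through the analog chain, the loop
#' engine in replay mode and the spectral analysis, and reports the dominant
#' frequency of the recorded signal. Mirrors the hardware bench validation
#' (scaled from a 24 h soak to a short run).
#'
#' @param duration_s Run length in seconds (default 60).
#' @param seed Session seed.
#' @param f0_hz Sine (and FIR centre) frequency in Hz.
#' @param fs Acquisition rate in Hz (single-channel analog input at the
#'   tick rate; default 1000).
#' @param f_min,f_max Search band for the dominant frequency (default
#'   1-50 Hz).
#' @return A list of class `stability_test`: `dominant_hz`, `psd`
#'   (a `spectral_estimate`), and `log` (the replay `session_log`).
#' @export
#' @examples
#' \donttest{
#' st <- stability_test(duration_s = 20)
#' st$dominant_hz
#' }
stability_test <- function(duration_s = 60, seed = 1, f0_hz = 10, fs = 1000,
                           f_min = 1, f_max = 50) {
  fixture <- make_fixture("sine", duration_s = duration_s, fs = fs,
                          freq_hz = f0_hz, amplitude = 0.5, seed = seed)
  config <- loop_config(
    tick_period_s = 1 / fs, n_channels = 1, seed = seed,
    conditions = tibble::tibble(condition_id = 1L, centre_freq_hz = f0_hz,
                                phase_shift_deg = 0, gain = 1),
    planner = planner_config(on_duration_s = duration_s, off_duration_s = 0),
    chain = chain_config(sample_rate_hz = fs),
    plant = plant_config(dt_s = 1 / fs)
  )
  log <- replay_session(fixture, config)
  psd <- estimate_psd(log$packets$raw_lfp - mean(log$packets$raw_lfp), fs)
  structure(
    list(dominant_hz = dominant_frequency(psd, f_min, f_max),
         psd = psd, log = log),
    class = "stability_test"
  )
}

#' @export
print.stability_test <- function(x, ...) {
  cat(sprintf("<stability_test> dominant frequency: %g Hz (%d-segment Welch PSD)\n",
              x$dominant_hz, attr(x$psd, "n_segments")))
  invisible(x)
}
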