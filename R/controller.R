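# Closed-loop algorithm: FIR band-pass/phase-shift kernel design, streaming
# controller step (convolution + LFP-to-light gain + rectification +
# saturation), frequency-response evaluation and kernel file I/O.

#' Design a phase-shifting band-pass FIR kernel
#'
#' Constructs the windowed-cosine (Gabor-type) kernel at the heart of the
#' closed-loop algorithm:
#' `h[k] = w[k] * cos(2*pi*f0*(k - c)/fs + phi)`,
#' with `w` a taper whose width sets the pass bandwidth and `c` the centre
#' tap. The taps are then corrected exactly (a 2x2 solve over the two
#' quadrature atoms) so the frequency response at `f0` has unit magnitude
#' and, after removing the nominal group delay of `(n_taps-1)/2` samples,
#' exactly the commanded phase. The causal kernel therefore delays the signal
#' by `(n_taps-1)/2` samples; the commanded phase shift is defined relative
#' to that delayed signal.
#'
#' @param f0_hz Centre frequency in Hz (0 < f0 < fs/2).
#' @param phase_deg Commanded phase shift in degrees; stored modulo 360.
#' @param fs_hz Sampling rate of the controller channel in Hz (default 500).
#' @param n_taps Odd kernel length; if `NULL`, derived from `bandwidth_hz`
#'   (default 121 taps at fs = 500 Hz, 6 Hz bandwidth).
#' @param bandwidth_hz Approximate -3 dB width of the pass band in Hz.
#' @param window Taper: `"hann"` (default), `"hamming"` or `"rect"`.
#' @return An object of class `fir_kernel`: the tap weights plus design
#'   metadata (`centre_freq_hz`, `phase_shift_deg`, `sample_rate_hz`,
#'   `bandwidth_hz`, `group_delay_samples`).
#' @export
#' @examples
#' k <- design_phase_shift_fir(10, 90)
#' Mod(frequency_response(k, 10))  # 1 by construction
design_phase_shift_fir <- function(f0_hz, phase_deg, fs_hz = 500,
                                   n_taps = NULL, bandwidth_hz = 6,
                                   window = c("hann", "hamming", "rect")) {
  window <- match.arg(window)
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  check_number(f0_hz, "f0_hz", lower = 0, strict_lower = TRUE)
  if (f0_hz >= fs_hz / 2) {
    abort_config("f0_hz (%g Hz) must lie below Nyquist (%g Hz)", f0_hz, fs_hz / 2)
  }
  check_number(phase_deg, "phase_deg")
  phase_deg <- phase_deg %% 360
  if (is.null(n_taps)) {
    check_number(bandwidth_hz, "bandwidth_hz", lower = 0, strict_lower = TRUE)
    # Hann main lobe: -3 dB full width ~ 1.45 / (window duration)
    n_taps <- ceiling(1.45 * fs_hz / bandwidth_hz)
    if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  }
  n_taps <- check_count(n_taps, "n_taps", lower = 3L)
  if (n_taps %% 2L == 0L) abort_config("n_taps must be odd (got %d)", n_taps)

  k <- seq_len(n_taps) - 1L
  ctr <- (n_taps - 1L) / 2
  w <- switch(window,
    hann = 0.5 - 0.5 * cos(2 * pi * k / (n_taps - 1L)),
    hamming = 0.54 - 0.46 * cos(2 * pi * k / (n_taps - 1L)),
    rect = rep(1, n_taps)
  )
  theta <- 2 * pi * f0_hz * (k - ctr) / fs_hz
  u <- w * cos(theta)
  v <- -w * sin(theta)
  omega <- 2 * pi * f0_hz / fs_hz
  hu <- sum(u * exp(-1i * omega * k))
  hv <- sum(v * exp(-1i * omega * k))
  # Solve alpha*Hu + beta*Hv = exp(i*(phi - omega*ctr)) so that after
  # removing the linear-phase (group delay) term the response at f0 is
  # exactly 1 * exp(i*phi).
  target <- exp(1i * (phase_deg * pi / 180 - omega * ctr))
  m <- matrix(c(Re(hu), Im(hu), Re(hv), Im(hv)), 2, 2)
  if (abs(det(m)) < 1e-12) {
    abort_config("degenerate kernel design at f0 = %g Hz, fs = %g Hz", f0_hz, fs_hz)
  }
  ab <- solve(m, c(Re(target), Im(target)))
  taps <- ab[1] * u + ab[2] * v

  structure(
    list(taps = taps, n_taps = n_taps, sample_rate_hz = fs_hz,
         centre_freq_hz = f0_hz, phase_shift_deg = phase_deg,
         bandwidth_hz = bandwidth_hz, window = window,
         group_delay_samples = ctr),
    class = "fir_kernel"
  )
}

#' Frequency response of an FIR kernel
#'
#' Exact discrete-time Fourier response by direct summation over the taps.
#'
#' @param kernel A [design_phase_shift_fir()] kernel.
#' @param freqs_hz Frequencies in Hz.
#' @return Complex response vector.
#' @export
frequency_response <- function(kernel, freqs_hz) {
  stopifnot(inherits(kernel, "fir_kernel"))
  k <- seq_len(kernel$n_taps) - 1L
  vapply(freqs_hz, function(f) {
    sum(kernel$taps * exp(-1i * 2 * pi * f / kernel$sample_rate_hz * k))
  }, complex(1))
}

#' Response phase after group-delay removal
#'
#' Phase (degrees, in `[0, 360)`) of the kernel's frequency response at the
#' given frequencies once the nominal linear-phase term of the centre tap has
#' been removed; at the centre frequency this equals the commanded phase
#' shift.
#'
#' @inheritParams frequency_response
#' @return Numeric vector of phases in degrees.
#' @export
kernel_phase_deg <- function(kernel, freqs_hz) {
  h <- frequency_response(kernel, freqs_hz)
  lin <- exp(1i * 2 * pi * freqs_hz / kernel$sample_rate_hz *
               kernel$group_delay_samples)
  (Arg(h * lin) * 180 / pi) %% 360
}

#' Controller configuration
#'
#' The full LFP-to-light conversion: FIR kernel, gain, rectification floor at
#' zero (an LED cannot emit negative light) and saturation ceiling.
#'
#' @param kernel A [design_phase_shift_fir()] kernel.
#' @param gain LFP-to-light conversion gain (light-units per volt, >= 0).
#' @param output_max Saturation ceiling in normalized light-units (> 0).
#' @param n_leds Number of LEDs replicating the command (default 1).
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(kernel, gain = 1, output_max = 1, n_leds = 1) {
  stopifnot(inherits(kernel, "fir_kernel"))
  check_number(gain, "gain", lower = 0)
  check_number(output_max, "output_max", lower = 0, strict_lower = TRUE)
  n_leds <- check_count(n_leds, "n_leds")
  structure(
    list(kernel = kernel, gain = gain, output_max = output_max, n_leds = n_leds),
    class = "controller_config"
  )
}

#' Fresh controller state
#'
#' A zeroed history buffer of the last `n_taps` input samples. The buffer is
#' re-zeroed at stimulation-epoch boundaries so conditions are independent.
#'
#' @param config A [controller_config()].
#' @return An object of class `controller_state`.
#' @export
controller_state <- function(config) {
  stopifnot(inherits(config, "controller_config"))
  structure(
    list(buffer = numeric(config$kernel$n_taps), enabled = TRUE),
    class = "controller_state"
  )
}

#' One controller tick
#'
#' Pushes the new sample into the history buffer, evaluates the FIR
#' convolution, and converts the algorithm output to a stimulation command by
#' gain, rectification at zero and saturation at `output_max`. Constant time
#' per call.
#'
#' @param state A [controller_state()].
#' @param sample New LFP sample in volts.
#' @param config The matching [controller_config()].
#' @return A list with `stim` (a `stim_command`: `intensity`, `n_leds`),
#'   `algo_out` (the raw convolution output in volts) and the updated
#'   `state`.
#' @export
controller_step <- function(state, sample, config) {
  buf <- c(sample, state$buffer[-length(state$buffer)])
  algo <- sum(config$kernel$taps * buf)
  intensity <- clamp(config$gain * algo, 0, config$output_max)
  state$buffer <- buf
  list(
    stim = stim_command(intensity, config$n_leds),
    algo_out = algo,
    state = state
  )
}

#' Stimulation command
#'
#' @param intensity Light intensity in normalized light-units (>= 0).
#' @param n_leds Number of LEDs driven with this intensity.
#' @return An object of class `stim_command`.
#' @export
stim_command <- function(intensity, n_leds = 1) {
  if (any(intensity < 0)) abort_config("stimulation intensity must be >= 0")
  structure(list(intensity = intensity, n_leds = as.integer(n_leds)),
            class = "stim_command")
}

#' Run the controller over a whole signal
#'
#' Batch equivalent of repeated [controller_step()] calls from a fresh state
#' (zero-padded history at the start).
#'
#' @param signal LFP samples in volts at the kernel sample rate.
#' @param config A [controller_config()].
#' @return A tibble with columns `algo_out` and `intensity`.
#' @export
controller_apply <- function(signal, config) {
  stopifnot(inherits(config, "controller_config"))
  taps <- config$kernel$taps
  n <- length(signal)
  if (n == 0L) return(tibble::tibble(algo_out = numeric(0), intensity = numeric(0)))
  padded <- c(numeric(length(taps) - 1L), signal)
  algo <- as.numeric(stats::filter(padded, taps, method = "convolution",
                                   sides = 1))[length(taps):(length(taps) + n - 1L)]
  tibble::tibble(
    algo_out = algo,
    intensity = clamp(config$gain * algo, 0, config$output_max)
  )
}

#' Write / read an FIR kernel as columnar text
#'
#' Plain two-column text (tap index, weight) with a commented header carrying
#' the design metadata, so kernels can be audited and compared across
#' implementations.
#'
#' @param kernel A `fir_kernel`.
#' @param path File path.
#' @return `write_kernel` returns `path` invisibly; `read_kernel` returns the
#'   reconstructed `fir_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "fir_kernel"))
  hdr <- c(
    sprintf("# sample_rate_hz: %s", format_num(kernel$sample_rate_hz)),
    sprintf("# centre_freq_hz: %s", format_num(kernel$centre_freq_hz)),
    sprintf("# phase_shift_deg: %s", format_num(kernel$phase_shift_deg)),
    sprintf("# bandwidth_hz: %s", format_num(kernel$bandwidth_hz)),
    sprintf("# window: %s", kernel$window),
    "# columns: tap weight"
  )
  rows <- sprintf("%d\t%s", seq_along(kernel$taps) - 1L, format_num(kernel$taps))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  lines <- readLines(path)
  hdr <- parse_header_lines(lines)
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("tap", "weight"))
  for (key in c("sample_rate_hz", "centre_freq_hz", "phase_shift_deg")) {
    if (is.null(hdr[[key]])) abort_data("kernel file missing header '%s'", key)
  }
  structure(
    list(taps = tab$weight, n_taps = nrow(tab),
         sample_rate_hz = as.numeric(hdr$sample_rate_hz),
         centre_freq_hz = as.numeric(hdr$centre_freq_hz),
         phase_shift_deg = as.numeric(hdr$phase_shift_deg),
         bandwidth_hz = as.numeric(hdr$bandwidth_hz %||% NA_real_),
         window = hdr$window %||% "unknown",
         group_delay_samples = (nrow(tab) - 1L) / 2),
    class = "fir_kernel"
  )
}

#' @export
tidy.fir_kernel <- function(x, ...) {
  tibble::tibble(tap = seq_along(x$taps) - 1L, weight = x$taps)
}

#' @export
glance.fir_kernel <- function(x, ...) {
  tibble::tibble(
    n_taps = x$n_taps,
    sample_rate_hz = x$sample_rate_hz,
    centre_freq_hz = x$centre_freq_hz,
    phase_shift_deg = x$phase_shift_deg,
    bandwidth_hz = x$bandwidth_hz,
    window = x$window,
    group_delay_s = x$group_delay_samples / x$sample_rate_hz,
    gain_at_f0 = Mod(frequency_response(x, x$centre_freq_hz)),
    phase_error_deg = {
      d <- (kernel_phase_deg(x, x$centre_freq_hz) - x$phase_shift_deg) %% 360
      min(d, 360 - d)
    }
  )
}

#' @export
print.fir_kernel <- function(x, ...) {
  cat(sprintf(
    "<fir_kernel> %d taps @ %g Hz | f0 = %g Hz, phase = %g deg, bw ~ %g Hz (%s window)\n",
    x$n_taps, x$sample_rate_hz, x$centre_freq_hz, x$phase_shift_deg,
    x$bandwidth_hz, x$window))
  invisible(x)
}

#' Plot an FIR kernel
#'
#' Tap weights (impulse response) or the magnitude/phase of the frequency
#' response.
#'
#' @param object A `fir_kernel`.
#' @param type `"taps"` or `"response"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fir_kernel <- function(object, type = c("taps", "response"), ...) {
  type <- match.arg(type)
  if (type == "taps") {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$tap, y = .data$weight)) +
      ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "tap", y = "weight",
                    title = sprintf("FIR kernel: f0 = %g Hz, phase = %g°",
                                    object$centre_freq_hz, object$phase_shift_deg))
  } else {
    f <- seq(0.1, object$sample_rate_hz / 2, by = 0.1)
    df <- tibble::tibble(freq_hz = f, gain = Mod(frequency_response(object, f)))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$gain)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$centre_freq_hz,
                          linetype = "dashed", colour = "grey50") +
      ggplot2::labs(x = "frequency (Hz)", y = "gain",
                    title = "FIR kernel magnitude response")
  }
}
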