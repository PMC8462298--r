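# Analog front-end model: level shifter, recursive (Butterworth) filters,
# ADC quantization, and the composed recording chain.

#' Level-shifter specification
#'
#' Describes the affine re-scaling stage that maps a bipolar analog input
#' (default +/-10 V) onto the unipolar ADC input range (default 0 to 3.3 V).
#' Inputs outside the rated input range saturate at the output rails, as the
#' physical circuit does.
#'
#' @param in_min,in_max Rated input range in volts.
#' @param out_min,out_max Output rails in volts.
#' @return An object of class `level_shifter_spec`.
#' @export
#' @examples
#' level_shift(c(-10, 0, 10), level_shifter_spec())
level_shifter_spec <- function(in_min = -10, in_max = 10,
                               out_min = 0, out_max = 3.3) {
  check_number(in_min, "in_min")
  check_number(in_max, "in_max")
  check_number(out_min, "out_min")
  check_number(out_max, "out_max")
  if (in_min >= in_max) abort_config("level shifter requires in_min < in_max")
  if (out_min >= out_max) abort_config("level shifter requires out_min < out_max")
  structure(
    list(in_min = in_min, in_max = in_max, out_min = out_min, out_max = out_max),
    class = "level_shifter_spec"
  )
}

#' Apply the level-shifting transform
#'
#' Affine map from the rated input range onto the output rails, with
#' saturation (clamping) outside the rails.
#'
#' @param x Input voltage(s).
#' @param spec A [level_shifter_spec()].
#' @return Numeric vector of output voltages, same length as `x`.
#' @export
level_shift <- function(x, spec = level_shifter_spec()) {
  if (!inherits(spec, "level_shifter_spec")) {
    abort_config("`spec` must be a level_shifter_spec")
  }
  slope <- (spec$out_max - spec$out_min) / (spec$in_max - spec$in_min)
  clamp(spec$out_min + (x - spec$in_min) * slope, spec$out_min, spec$out_max)
}

#' Recursive filter specification
#'
#' Parameters for a discrete-time Butterworth low- or high-pass stage. The
#' stated cutoff is the -3 dB frequency (magnitude 1/sqrt(2) of the passband
#' value).
#'
#' @param kind `"lowpass"` or `"highpass"`.
#' @param order Filter order (>= 1).
#' @param cutoff_hz Cutoff frequency in Hz; must lie strictly below Nyquist.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `recursive_filter_spec`.
#' @export
recursive_filter_spec <- function(kind = c("lowpass", "highpass"),
                                  order, cutoff_hz, sample_rate_hz) {
  kind <- match.arg(kind)
  order <- check_count(order, "order")
  check_number(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  check_number(cutoff_hz, "cutoff_hz", lower = 0, strict_lower = TRUE)
  if (cutoff_hz >= sample_rate_hz / 2) {
    abort_config("cutoff_hz (%g Hz) must lie below Nyquist (%g Hz)",
                 cutoff_hz, sample_rate_hz / 2)
  }
  structure(
    list(kind = kind, order = order, cutoff_hz = cutoff_hz,
         sample_rate_hz = sample_rate_hz),
    class = "recursive_filter_spec"
  )
}

#' Design a recursive (Butterworth) filter
#'
#' Returns transfer-function coefficients of a digital Butterworth filter
#' whose magnitude response is 1/sqrt(2) of the passband value at the
#' specified cutoff.
#'
#' @param spec A [recursive_filter_spec()].
#' @return An object of class `recursive_filter` with elements `b`
#'   (numerator), `a` (denominator, `a[1] = 1`) and `spec`.
#' @export
#' @examples
#' aaf <- design_recursive_filter(
#'   recursive_filter_spec("lowpass", 2, 250, 1000))
#' Mod(filter_response(aaf, 250))  # ~ 0.707
design_recursive_filter <- function(spec) {
  if (!inherits(spec, "recursive_filter_spec")) {
    abort_config("`spec` must be a recursive_filter_spec")
  }
  type <- switch(spec$kind, lowpass = "low", highpass = "high")
  ba <- signal::butter(spec$order, spec$cutoff_hz / (spec$sample_rate_hz / 2),
                       type = type)
  structure(
    list(b = as.numeric(ba$b), a = as.numeric(ba$a), spec = spec),
    class = "recursive_filter"
  )
}

#' Frequency response of a recursive filter
#'
#' Evaluates the transfer function H(z) on the unit circle at the requested
#' physical frequencies by direct polynomial evaluation.
#'
#' @param filt A `recursive_filter` from [design_recursive_filter()].
#' @param freqs_hz Frequencies in Hz.
#' @return Complex vector of responses.
#' @export
filter_response <- function(filt, freqs_hz) {
  stopifnot(inherits(filt, "recursive_filter"))
  fs <- filt$spec$sample_rate_hz
  vapply(freqs_hz, function(f) {
    zn <- exp(-1i * 2 * pi * f / fs * (seq_along(filt$b) - 1))
    zd <- exp(-1i * 2 * pi * f / fs * (seq_along(filt$a) - 1))
    sum(filt$b * zn) / sum(filt$a * zd)
  }, complex(1))
}

#' Streaming filter state
#'
#' Internal state for one-sample-at-a-time application of a recursive filter
#' (direct form II transposed). By default the state is zero; `dc_input`
#' warm-starts the filter in its steady state for a constant input, the way
#' a settled analog stage sits at its DC operating point.
#'
#' @param filt A `recursive_filter`.
#' @param dc_input Constant input the filter is assumed to have settled at.
#' @return Numeric state vector.
#' @export
filter_state <- function(filt, dc_input = 0) {
  stopifnot(inherits(filt, "recursive_filter"))
  n <- max(length(filt$a), length(filt$b))
  b <- c(filt$b, numeric(n - length(filt$b)))
  a <- c(filt$a, numeric(n - length(filt$a)))
  if (dc_input == 0) return(numeric(n - 1L))
  y0 <- dc_input * sum(b) / sum(a)
  # steady DF2T state: z_i = sum_{k > i} (b_k u - a_k y)
  rev(cumsum(rev(b[-1] * dc_input - a[-1] * y0)))
}

# DC gain of a recursive filter
filter_dc_gain <- function(filt) sum(filt$b) / sum(filt$a)

#' Advance a streaming filter by one sample
#'
#' @param state State from [filter_state()] or a previous call.
#' @param sample One input sample.
#' @param filt The `recursive_filter` the state belongs to.
#' @return A list with `output` (one sample) and the updated `state`.
#' @export
filter_step <- function(state, sample, filt) {
  n <- length(state) + 1L
  b <- c(filt$b, numeric(n - length(filt$b)))
  a <- c(filt$a, numeric(n - length(filt$a)))
  y <- b[1] * sample + state[1]
  ns <- state
  if (n > 2L) {
    ns[seq_len(n - 2L)] <- b[2:(n - 1L)] * sample + state[2:(n - 1L)] - a[2:(n - 1L)] * y
  }
  ns[n - 1L] <- b[n] * sample - a[n] * y
  list(output = y, state = ns)
}

#' Apply a recursive filter to a whole signal
#'
#' Causal application with zero initial conditions; equivalent to feeding the
#' samples one at a time through [filter_step()].
#'
#' @param signal Numeric input samples.
#' @param filt A `recursive_filter`.
#' @return Filtered samples, same length as the input.
#' @export
apply_filter <- function(signal, filt) {
  stopifnot(inherits(filt, "recursive_filter"))
  if (length(signal) == 0L) return(numeric(0))
  as.numeric(signal::filter(filt$b, filt$a, signal))
}

#' ADC specification
#'
#' Uniform mid-rise quantizer over a stated voltage range; inputs outside the
#' range saturate at the end codes.
#'
#' @param n_bits Resolution in bits (>= 1).
#' @param v_min,v_max Conversion range in volts.
#' @return An object of class `adc_spec`.
#' @export
adc_spec <- function(n_bits = 12, v_min = 0, v_max = 3.3) {
  n_bits <- check_count(n_bits, "n_bits")
  check_number(v_min, "v_min")
  check_number(v_max, "v_max")
  if (v_min >= v_max) abort_config("ADC requires v_min < v_max")
  structure(list(n_bits = n_bits, v_min = v_min, v_max = v_max),
            class = "adc_spec")
}

#' Quantize a voltage
#'
#' Uniform mid-rise quantization with clamping; the reconstruction error for
#' any in-range input is at most half a step.
#'
#' @param x Input voltage(s).
#' @param spec An [adc_spec()].
#' @return A tibble with columns `code` (integer) and `volts` (reconstructed
#'   value), one row per input sample.
#' @export
quantize <- function(x, spec = adc_spec()) {
  if (!inherits(spec, "adc_spec")) abort_config("`spec` must be an adc_spec")
  n_codes <- 2^spec$n_bits
  step <- (spec$v_max - spec$v_min) / n_codes
  code <- clamp(floor((x - spec$v_min) / step), 0, n_codes - 1)
  tibble::tibble(code = as.integer(code),
                 volts = spec$v_min + (code + 0.5) * step)
}

#' Recording-chain configuration
#'
#' Composes the analog front end in its physical order: the recording
#' amplifier band-pass cascade on the tissue side (2nd-order high-pass then
#' 1st-order low-pass, unity gain by default), the level shifter, the
#' 2nd-order 250 Hz anti-aliasing filter, and the ADC. Stages can be
#' individually disabled for tests. All recursive stages run at the loop
#' sample rate.
#'
#' @param sample_rate_hz Rate at which the chain is clocked (the loop tick
#'   rate; default 1000 Hz).
#' @param amp_highpass,amp_lowpass,aaf [recursive_filter_spec()]s for the
#'   amplifier corners and the anti-aliasing filter; defaults are 1 Hz
#'   high-pass (order 2), 200 Hz low-pass (order 1) and 250 Hz low-pass
#'   (order 2).
#' @param amp_gain Scalar amplifier gain (default 1).
#' @param level_shifter A [level_shifter_spec()].
#' @param adc An [adc_spec()].
#' @param enabled_stages Character subset of
#'   `c("amp_highpass", "amp_lowpass", "level_shifter", "aaf", "adc")`.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(sample_rate_hz = 1000,
                         amp_highpass = recursive_filter_spec("highpass", 2, 1, sample_rate_hz),
                         amp_lowpass = recursive_filter_spec("lowpass", 1, 200, sample_rate_hz),
                         amp_gain = 1,
                         level_shifter = level_shifter_spec(),
                         aaf = recursive_filter_spec("lowpass", 2, 250, sample_rate_hz),
                         adc = adc_spec(),
                         enabled_stages = c("amp_highpass", "amp_lowpass",
                                            "level_shifter", "aaf", "adc")) {
  check_number(sample_rate_hz, "sample_rate_hz", lower = 0, strict_lower = TRUE)
  stages <- c("amp_highpass", "amp_lowpass", "level_shifter", "aaf", "adc")
  bad <- setdiff(enabled_stages, stages)
  if (length(bad)) abort_config("unknown chain stage(s): %s", toString(bad))
  for (nm in c("amp_highpass", "amp_lowpass", "aaf")) {
    sp <- get(nm)
    if (!inherits(sp, "recursive_filter_spec")) {
      abort_config("`%s` must be a recursive_filter_spec", nm)
    }
    if (sp$sample_rate_hz != sample_rate_hz) {
      abort_config("stage `%s` sample rate (%g Hz) must equal the chain rate (%g Hz)",
                   nm, sp$sample_rate_hz, sample_rate_hz)
    }
  }
  check_number(amp_gain, "amp_gain")
  structure(
    list(sample_rate_hz = sample_rate_hz,
         amp_highpass = amp_highpass, amp_lowpass = amp_lowpass,
         amp_gain = amp_gain, level_shifter = level_shifter,
         aaf = aaf, adc = adc, enabled_stages = enabled_stages),
    class = "chain_config"
  )
}

chain_stage_enabled <- function(config, stage) stage %in% config$enabled_stages

#' Streaming state for the recording chain
#'
#' @param config A [chain_config()].
#' @return An object of class `chain_state` holding designed filters and
#'   per-stage streaming states.
#' @export
chain_state <- function(config) {
  stopifnot(inherits(config, "chain_config"))
  filts <- list(
    amp_highpass = design_recursive_filter(config$amp_highpass),
    amp_lowpass = design_recursive_filter(config$amp_lowpass),
    aaf = design_recursive_filter(config$aaf)
  )
  # warm-start each stage at its DC operating point for a 0 V tissue input
  # (a settled analog chain, so e.g. the level-shifter offset causes no
  # start-up transient)
  dc <- chain_dc_levels(config, filts)
  states <- list(
    amp_highpass = filter_state(filts$amp_highpass, dc$amp_highpass),
    amp_lowpass = filter_state(filts$amp_lowpass, dc$amp_lowpass),
    aaf = filter_state(filts$aaf, dc$aaf)
  )
  structure(
    list(config = config, filters = filts, states = states),
    class = "chain_state"
  )
}

# DC value entering each recursive stage when the tissue input sits at 0 V.
chain_dc_levels <- function(config, filts) {
  dc <- 0
  out <- list(amp_highpass = 0, amp_lowpass = 0, aaf = 0)
  if (chain_stage_enabled(config, "amp_highpass")) {
    out$amp_highpass <- dc
    dc <- dc * filter_dc_gain(filts$amp_highpass)
  }
  if (chain_stage_enabled(config, "amp_lowpass")) {
    out$amp_lowpass <- dc
    dc <- dc * filter_dc_gain(filts$amp_lowpass)
  }
  dc <- dc * config$amp_gain
  if (chain_stage_enabled(config, "level_shifter")) {
    dc <- level_shift(dc, config$level_shifter)
  }
  if (chain_stage_enabled(config, "aaf")) {
    out$aaf <- dc
  }
  out
}

#' Advance the recording chain by one sample
#'
#' @param state A [chain_state()].
#' @param sample Tissue-side voltage sample.
#' @return A list with `output` (recorded voltage after the enabled stages)
#'   and the updated `state`.
#' @export
chain_step <- function(state, sample) {
  cfg <- state$config
  s <- sample
  for (nm in c("amp_highpass", "amp_lowpass")) {
    if (chain_stage_enabled(cfg, nm)) {
      st <- filter_step(state$states[[nm]], s, state$filters[[nm]])
      s <- st$output
      state$states[[nm]] <- st$state
    }
  }
  s <- s * cfg$amp_gain
  if (chain_stage_enabled(cfg, "level_shifter")) {
    s <- level_shift(s, cfg$level_shifter)
  }
  if (chain_stage_enabled(cfg, "aaf")) {
    st <- filter_step(state$states$aaf, s, state$filters$aaf)
    s <- st$output
    state$states$aaf <- st$state
  }
  if (chain_stage_enabled(cfg, "adc")) {
    s <- quantize(s, cfg$adc)$volts
  }
  list(output = s, state = state)
}

#' Run a whole signal through the recording chain
#'
#' Vectorised equivalent of repeated [chain_step()] calls from a fresh state.
#'
#' @param signal Tissue-side voltage samples at the chain sample rate.
#' @param config A [chain_config()].
#' @return Recorded samples (reconstructed volts after the ADC when enabled).
#' @export
chain_apply <- function(signal, config) {
  stopifnot(inherits(config, "chain_config"))
  filts <- list(
    amp_highpass = design_recursive_filter(config$amp_highpass),
    amp_lowpass = design_recursive_filter(config$amp_lowpass),
    aaf = design_recursive_filter(config$aaf)
  )
  dc <- chain_dc_levels(config, filts)
  # filtering around the DC operating point is equivalent to warm-started
  # streaming application
  settled <- function(s, filt, u0) {
    u0 * filter_dc_gain(filt) + apply_filter(s - u0, filt)
  }
  s <- signal
  if (chain_stage_enabled(config, "amp_highpass")) {
    s <- settled(s, filts$amp_highpass, dc$amp_highpass)
  }
  if (chain_stage_enabled(config, "amp_lowpass")) {
    s <- settled(s, filts$amp_lowpass, dc$amp_lowpass)
  }
  s <- s * config$amp_gain
  if (chain_stage_enabled(config, "level_shifter")) {
    s <- level_shift(s, config$level_shifter)
  }
  if (chain_stage_enabled(config, "aaf")) {
    s <- settled(s, filts$aaf, dc$aaf)
  }
  if (chain_stage_enabled(config, "adc")) {
    s <- quantize(s, config$adc)$volts
  }
  s
}

# Recorded value of a 0 V tissue input once the chain has settled: the
# emulated firmware subtracts this DC operating point (the mid-scale ADC
# code when the ADC is enabled) before the FIR so the controller sees a
# zero-mean signal.
chain_dc_offset <- function(config) {
  off <- if (chain_stage_enabled(config, "level_shifter")) {
    (config$level_shifter$out_min + config$level_shifter$out_max) / 2
  } else {
    0
  }
  if (chain_stage_enabled(config, "adc")) {
    off <- quantize(off, config$adc)$volts
  }
  off
}
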