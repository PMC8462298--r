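# Internal helpers: error classes, seed substreams, numeric utilities.

abort_config <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "phasestim_config_error")
}

abort_data <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "phasestim_data_error")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is_scalar_number(x)) {
    abort_config("`%s` must be a single finite number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort_config(
      "`%s` = %g violates the constraint %s%s, %s%s", name, x,
      if (strict_lower) "(" else "[", lower, upper,
      if (strict_upper) ")" else "]"
    )
  }
  x
}

check_count <- function(x, name, lower = 1L) {
  if (!is_scalar_number(x) || x != round(x) || x < lower) {
    abort_config("`%s` must be an integer >= %d", name, lower)
  }
  as.integer(x)
}

# Named substreams derived from one session seed so that no module reads
# ambient randomness. Streams are spaced by a fixed odd stride and folded
# into the 31-bit range R's set.seed() accepts.
.stream_ids <- c(plan = 1L, plant_process = 2L, plant_measurement = 3L,
                 burst = 4L, fixture = 5L, analysis = 6L)

derive_seed <- function(seed, stream) {
  if (!stream %in% names(.stream_ids)) {
    abort_config("unknown seed stream '%s'", stream)
  }
  s <- (as.double(seed) %% 2147483647) * 2654435761
  s <- (s + .stream_ids[[stream]] * 40503) %% 2147483647
  as.integer(s)
}

# Evaluate `expr` under a fixed, named RNG without disturbing the caller's
# RNG state; the generator kind is pinned for cross-platform reproducibility.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

format_num <- function(x) sprintf("%.15g", x)
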