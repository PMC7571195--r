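# Internal helpers shared across modules.

#' Canonical feature order
#'
#' The sixteen feature channels used throughout the pipeline, in the fixed
#' order that determines spike-raster row blocks and input-neuron placement:
#' ten facial landmark distances `f1..f10` followed by the six peripheral
#' physiological channels.
#'
#' @return Character vector of length 16.
#' @export
valence_features <- function() {
  c(paste0("f", 1:10),
    "hrv", "resp_variability", "resp_depth", "temperature", "gsr", "pupil")
}

#' @rdname valence_features
#' @export
facial_features <- function() paste0("f", 1:10)

#' @rdname valence_features
#' @export
peripheral_features <- function() {
  c("hrv", "resp_variability", "resp_depth", "temperature", "gsr", "pupil")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Deterministic substream seed: keeps results < 2^31 and decorrelates the
# stage-level streams (simulate / reservoir / evaluation) from one another.
derive_seed <- function(seed, offset) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + offset) %%
               2147483647)
}

stop_invalid <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid("`%s` must be a single number", name)
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop_invalid("`%s` = %g violates bound %s%g, %g%s", name, x,
                 if (strict_lower) "(" else "[", lower, upper,
                 if (strict_upper) ")" else "]")
  invisible(x)
}

# Sparse event series (value known at irregular times), used for RR intervals
# and respiration cycle features.
event_series <- function(time, value) {
  stopifnot(length(time) == length(value))
  structure(data.frame(time = as.numeric(time), value = as.numeric(value)),
            class = c("event_series", "data.frame"))
}

is_event_series <- function(x) inherits(x, "event_series")
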