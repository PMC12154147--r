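# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation error that names the offending field, so callers of the
# generators can see exactly which part of a spec was rejected.
stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_scalar_pos <- function(x, field, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_field(field, "must be a single numeric value")
  if (strict && x <= 0) stop_field(field, "must be > 0")
  if (!strict && x < 0) stop_field(field, "must be >= 0")
  invisible(x)
}

check_nonneg_vec <- function(x, field) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0))
    stop_field(field, "must be non-negative numeric")
  invisible(x)
}

# RMS of a vector; empty input is defined as 0 (an empty dose bin carries no
# energy).
rms <- function(x) if (length(x) == 0L) 0 else sqrt(mean(x^2))

# Population (n-denominator) standard deviation.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
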