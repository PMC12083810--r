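#' @keywords internal
"_PACKAGE"

# Internal validation helpers. Errors name the offending argument so that
# callers of the user-facing constructors get actionable messages.

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

assert_positive <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_field(field, "must be a single finite value > 0")
  }
  invisible(x)
}

assert_count <- function(x, field, positive = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= if (positive) 1 else 0 && x == round(x)
  if (!ok) {
    stop_field(field, if (positive) "must be a positive integer" else
      "must be a non-negative integer")
  }
  invisible(as.integer(x))
}

assert_probability <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 || x >= 1) {
    stop_field(field, "must lie strictly between 0 and 1")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# round-half-away-from-zero at `digits`; base round() ties to even, which
# does not match how report tables are conventionally printed
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
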