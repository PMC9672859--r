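# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

abort_flimr <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "flimr_error"), ...)
}

#' Validate a uniform time grid
#'
#' Checks that a vector of bin-centre times is strictly increasing and
#' uniformly spaced to a relative tolerance of 1e-9, as required by the
#' FFT convolution scheme.
#'
#' @param time_ns Numeric vector of bin-centre times in nanoseconds.
#' @param min_bins Minimum number of bins required.
#' @return The bin width `dt` in nanoseconds, invisibly usable.
#' @keywords internal
#' @noRd
validate_time_grid <- function(time_ns, min_bins = 2L) {
  if (length(time_ns) < min_bins) {
    abort_flimr(
      sprintf("time grid has %d bins; at least %d required", length(time_ns), min_bins),
      "flimr_invalid_grid"
    )
  }
  if (length(time_ns) == 1L) return(NA_real_)
  d <- diff(time_ns)
  dt <- d[1]
  if (dt <= 0 || any(abs(d - dt) > 1e-9 * max(abs(dt), 1))) {
    abort_flimr("time grid must be uniformly spaced with positive bin width",
                "flimr_invalid_grid")
  }
  dt
}

# Next power of two >= n (n >= 1).
next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

# Extract (time, value) columns from a decay data frame. Accepts `counts`,
# `expected`, `value` or `response` as the value column.
decay_cols <- function(df, value_cols = c("counts", "expected", "value", "response")) {
  if (!is.data.frame(df) || !"time_ns" %in% names(df)) {
    abort_flimr("expected a data frame with a `time_ns` column", "flimr_format_error")
  }
  vc <- intersect(value_cols, names(df))
  if (length(vc) == 0L) {
    abort_flimr(
      sprintf("no value column found (looked for: %s)", paste(value_cols, collapse = ", ")),
      "flimr_format_error"
    )
  }
  list(time_ns = df[["time_ns"]], value = df[[vc[1]]], value_name = vc[1])
}
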