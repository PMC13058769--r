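# Internal helpers shared across modules.

#' Round half-up to a fixed number of decimals
#'
#' Display convention for reported percentages and NNE values; base
#' `round()` uses banker's rounding, which does not reproduce printed
#' clinical tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

hours_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

# Minute-resolution, timezone-naive timestamps: everything is POSIXct in UTC.
round_minute <- function(t) {
  as.POSIXct(round(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

parse_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out) & !is.na(x))
    if (length(idx) == 0) break
    out[idx] <- as.POSIXct(strptime(x[idx], fmt, tz = "UTC"))
  }
  out
}

format_timestamp <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

calendar_day <- function(t) {
  as.integer(floor(as.numeric(t) / 86400))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
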