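# Time axis: all event times are integer milliseconds on the same axis as
# an admission's admit_time (de-identified offsets); day windows are
# consecutive 24 h periods starting at admission.

MS_PER_HOUR <- 3600 * 1000
MS_PER_DAY <- 24 * MS_PER_HOUR

#' Day index of a timestamp relative to ICU admission
#'
#' Day `d` covers the half-open window `[d * 24h, (d + 1) * 24h)` measured
#' from the admission time.
#'
#' @param time_ms Numeric vector of timestamps in milliseconds.
#' @param admit_time_ms Admission time on the same axis (default 0).
#' @return Integer day indices (day 0 is the first 24 h of the stay).
#' @export
day_index <- function(time_ms, admit_time_ms = 0) {
  as.integer(floor((time_ms - admit_time_ms) / MS_PER_DAY))
}

# Does the dose/infusion interval [start, stop] touch day `day`?
# Point doses (start == stop) belong to the window containing the point;
# a nonzero-length interval ending exactly at a window boundary does not
# spill into the next window.
interval_on_day <- function(start, stop, day, admit = 0) {
  d0 <- admit + day * MS_PER_DAY
  d1 <- d0 + MS_PER_DAY
  ifelse(start == stop, start >= d0 & start < d1, start < d1 & stop > d0)
}

# All day indices covered by an interval, clamped to [0, last_day].
days_covered <- function(start, stop, last_day, admit = 0) {
  first <- day_index(start, admit)
  last <- if (stop == start) first else as.integer(ceiling((stop - admit) / MS_PER_DAY) - 1)
  lo <- max(first, 0L)
  hi <- min(last, last_day)
  if (lo > hi) integer(0) else seq.int(lo, hi)
}

# Hours of overlap between [start, stop] and day window `day`.
hours_on_day <- function(start, stop, day, admit = 0) {
  d0 <- admit + day * MS_PER_DAY
  d1 <- d0 + MS_PER_DAY
  pmax(0, (pmin(stop, d1) - pmax(start, d0))) / MS_PER_HOUR
}

#' Round half away from zero
#'
#' Fixed-precision rounding in which exact halves round up (`round()` in
#' base R rounds half to even). Used for all printed percentages.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a numerator over a denominator
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimal places (default 1, half-up).
#' @return Numeric percentage; `NA` when `den` is 0.
#' @export
pct_value <- function(num, den, digits = 1) {
  ifelse(den == 0, NA_real_, round_half_up(100 * num / den, digits))
}

#' Format a percentage the way cohort tables print it
#'
#' One decimal place, halves rounded up: `format_pct(4272, 9083)` is
#' `"47.0"`.
#'
#' @inheritParams pct_value
#' @return Character vector.
#' @export
format_pct <- function(num, den, digits = 1) {
  v <- pct_value(num, den, digits)
  ifelse(is.na(v), NA_character_, sprintf(paste0("%.", digits, "f"), v))
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Internal stopifnot with a formatted message.
fail_if <- function(cond, fmt, ...) {
  if (isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(NULL)
}
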