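#' Uniformly sampled time series
#'
#' The universal signal carrier of the package: a tibble with a `time` column
#' (seconds) and a `value` column in SI units (volts for potentials, amperes
#' for currents). The physical unit is kept as an attribute so that file
#' writers and plots can label axes; all computation is done in SI.
#'
#' @param value numeric vector of samples (SI units).
#' @param dt sample interval in seconds (> 0).
#' @param t0 time of the first sample in seconds.
#' @param unit unit tag, one of `"V"`, `"A"`, `"S"`, `"1"` (dimensionless).
#' @param time optional explicit time vector; overrides `dt`/`t0` and must be
#'   uniformly spaced.
#'
#' @return A tibble of class `cleft_ts` with columns `time` and `value`.
#' @examples
#' s <- cleft_ts(sin(seq(0, 1, by = 0.01)), dt = 1e-4, unit = "V")
#' ts_dt(s)
#' @export
cleft_ts <- function(value, dt = NULL, t0 = 0, unit = "V", time = NULL) {
  if (is.null(time)) {
    if (is.null(dt)) abort("either `dt` or `time` must be given")
    time <- t0 + dt * (seq_along(value) - 1L)
  }
  x <- tibble::tibble(time = as.numeric(time), value = as.numeric(value))
  attr(x, "unit") <- unit
  class(x) <- c("cleft_ts", class(x))
  validate_cleft_ts(x)
}

validate_cleft_ts <- function(x) {
  if (nrow(x) < 2L) abort("a time series needs at least 2 samples")
  if (!all(is.finite(x$value))) abort("all samples must be finite")
  dts <- diff(x$time)
  dt <- stats::median(dts)
  if (dt <= 0) abort("sample interval must be positive")
  bad <- which(abs(dts - dt) > 1e-6 * dt)
  if (length(bad) > 0L) {
    abort(sprintf("non-uniform time base: first offending index %d", bad[1] + 1L))
  }
  x
}

#' Coerce a data frame to a cleft time series
#'
#' @param x a data frame with a `time` column and exactly one signal column,
#'   or an existing `cleft_ts`.
#' @param unit unit tag applied when `x` carries none.
#' @return a `cleft_ts` tibble.
#' @export
as_cleft_ts <- function(x, unit = NULL) {
  if (inherits(x, "cleft_ts") && is.null(unit)) return(validate_cleft_ts(x))
  stopifnot(is.data.frame(x), "time" %in% names(x))
  vcol <- setdiff(names(x), "time")
  if (length(vcol) != 1L) abort("expected exactly one signal column besides `time`")
  cleft_ts(x[[vcol]], time = x$time, unit = unit %||% attr(x, "unit") %||% "1")
}

#' Sample interval, start time and unit of a time series
#' @param x a `cleft_ts` (or data frame with uniform `time`).
#' @return `ts_dt()`: the sample interval (s); `ts_t0()`: the first sample
#'   time (s); `ts_unit()`: the unit tag.
#' @export
ts_dt <- function(x) stats::median(diff(x$time))

#' @rdname ts_dt
#' @export
ts_t0 <- function(x) x$time[1]

#' @rdname ts_dt
#' @export
ts_unit <- function(x) attr(x, "unit") %||% "1"

# rebuild a cleft_ts on the time base of `template` with new values
ts_like <- function(template, value, unit = NULL) {
  cleft_ts(value, time = template$time, unit = unit %||% ts_unit(template))
}

check_aligned <- function(...) {
  xs <- list(...)
  t1 <- xs[[1]]$time
  for (x in xs[-1]) {
    if (nrow(x) != length(t1) || max(abs(x$time - t1)) > 1e-9 * ts_dt(xs[[1]])) {
      abort("time series are not aligned (same t0, dt and length required)")
    }
  }
  invisible(TRUE)
}

#' Full width at half maximum of a pulse
#'
#' Measures the width of the dominant deflection of `x` about its baseline
#' (taken from the first sample), using linear interpolation between samples
#' at the half-maximum crossings.
#'
#' @param x a `cleft_ts`.
#' @return width in seconds.
#' @export
ts_fwhm <- function(x) {
  v <- x$value - x$value[1]
  if (max(abs(v)) == 0) return(NA_real_)
  if (abs(min(v)) > abs(max(v))) v <- -v
  pk <- which.max(v)
  half <- v[pk] / 2
  il <- which(v[seq_len(pk)] < half)
  ir <- which(v[seq(pk, length(v))] < half)
  if (length(il) == 0L || length(ir) == 0L) return(NA_real_)
  i1 <- max(il)                       # last below-half sample before the peak
  i2 <- pk + min(ir) - 1L             # first below-half sample after the peak
  dt <- ts_dt(x)
  tl <- x$time[i1] + dt * (half - v[i1]) / (v[i1 + 1] - v[i1])
  tr <- x$time[i2 - 1L] + dt * (half - v[i2 - 1L]) / (v[i2] - v[i2 - 1L])
  tr - tl
}

# parabolic (3-point) refinement of an extremum at index i; returns c(t, v)
parabolic_peak <- function(time, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n) return(c(time[i], v[i]))
  y1 <- v[i - 1L]; y2 <- v[i]; y3 <- v[i + 1L]
  den <- y1 - 2 * y2 + y3
  if (den == 0) return(c(time[i], v[i]))
  d <- 0.5 * (y1 - y3) / den
  dt <- time[2] - time[1]
  c(time[i] + d * dt, y2 - 0.25 * (y1 - y3) * d)
}

#' @export
print.cleft_ts <- function(x, ...) {
  cat(sprintf("<cleft_ts: %d samples, dt = %.3g s, unit = %s>\n",
              nrow(x), ts_dt(x), ts_unit(x)))
  NextMethod()
}
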