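# Tabular time-series IO. Files are tab-separated text with a header naming
# the time column in ms and each signal column with a unit suffix
# (v_pre_mV, i_post_nA, ...); values are written at full double precision so
# write -> read round-trips are exact to floating-point rounding.

.unit_suffix <- c(V = "mV", A = "nA", S = "uS", `1` = "au")
.unit_scale <- c(V = 1e3, A = 1e9, S = 1e6, `1` = 1)

#' Write and read a time series as delimited text
#'
#' `write_timeseries()` stores a `cleft_ts` as a two-column tab-separated
#' file, time in ms and the signal in the conventional unit implied by its
#' SI unit tag (V -> mV, A -> nA, S -> uS, dimensionless -> au).
#' `read_timeseries()` parses the unit from the header suffix, converts back
#' to SI, and checks that the time base is uniform (failing with the index
#' of the first gap).
#'
#' @param x a `cleft_ts`.
#' @param path file path.
#' @param name column base name for the signal (e.g. `"v_pre"`).
#' @return `write_timeseries()`: `path`, invisibly; `read_timeseries()`: a
#'   `cleft_ts` in SI units.
#' @export
write_timeseries <- function(x, path, name = "value") {
  u <- ts_unit(x)
  if (!u %in% names(.unit_suffix)) {
    abort(sprintf("unknown unit tag '%s': cannot choose a file unit", u))
  }
  df <- tibble::tibble(time_ms = x$time * 1e3,
                       v = x$value * .unit_scale[[u]])
  names(df)[2] <- paste0(name, "_", .unit_suffix[[u]])
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  if (names(df)[1] != "time_ms" || ncol(df) != 2L) {
    abort("expected a two-column file with a 'time_ms' column first")
  }
  suffix <- sub(".*_", "", names(df)[2])
  u <- names(.unit_suffix)[match(suffix, .unit_suffix)]
  if (is.na(u)) abort(sprintf("unknown unit tag '%s' in column '%s'", suffix, names(df)[2]))
  time <- df$time_ms / 1e3
  dts <- diff(time)
  dt <- stats::median(dts)
  bad <- which(abs(dts - dt) > 1e-9 * dt)
  if (length(bad) > 0L) {
    abort(sprintf("non-uniform time base in '%s': first offending index %d", path, bad[1] + 1L))
  }
  cleft_ts(df[[2]] / .unit_scale[[u]], time = time, unit = u)
}
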