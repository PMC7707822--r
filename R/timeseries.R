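#' Uniformly sampled scalar signal
#'
#' The basic container for EMG traces (raw or integrated) and resampled
#' coordinate traces. Sample `i` (1-based) covers the half-open interval
#' `[t0 + (i-1)/fs, t0 + i/fs)`; its nominal time is the interval start.
#'
#' @param values numeric vector, all finite, length >= 1.
#' @param fs sampling rate in Hz, > 0.
#' @param t0 time of the first sample in seconds.
#' @return An object of class `loco_ts`: a list with elements `values`,
#'   `fs`, `t0`.
#' @examples
#' x <- time_series(sin(2 * pi * 8 * seq(0, 1, by = 1e-3)), fs = 1000)
#' ts_duration(x)
#' @export
time_series <- function(values, fs, t0 = 0) {
  if (!is_scalar_num(fs) || fs <= 0) stop_parameter("fs must be a finite scalar > 0")
  if (!is_scalar_num(t0)) stop_parameter("t0 must be a finite scalar")
  values <- as.numeric(values)
  if (length(values) < 1L) stop_validation("time series must contain at least one sample")
  if (anyNA(values) || any(!is.finite(values)))
    stop_validation("time series contains non-finite samples")
  structure(list(values = values, fs = fs, t0 = t0), class = "loco_ts")
}

#' @export
print.loco_ts <- function(x, ...) {
  cat(sprintf("<loco_ts> %d samples @ %g Hz, t0 = %g s, duration %g s\n",
              length(x$values), x$fs, x$t0, ts_duration(x)))
  invisible(x)
}

#' Sample times of a time series
#' @param x a `loco_ts`.
#' @return numeric vector of the nominal time of each sample (interval starts).
#' @export
ts_times <- function(x) x$t0 + (seq_along(x$values) - 1L) / x$fs

#' Duration of a time series in seconds
#' @param x a `loco_ts`.
#' @return length of the record in seconds (`n / fs`).
#' @export
ts_duration <- function(x) length(x$values) / x$fs

#' Extract a time window from a time series
#'
#' Keeps the samples whose nominal times fall in `[from, to)`.
#'
#' @param x a `loco_ts`.
#' @param from,to window bounds in seconds.
#' @return a `loco_ts` covering the window.
#' @export
ts_window <- function(x, from, to) {
  if (!is_scalar_num(from) || !is_scalar_num(to) || to <= from)
    stop_parameter("need finite from < to")
  tt <- ts_times(x)
  keep <- tt >= from & tt < to
  if (!any(keep)) stop_parameter("window [%g, %g) contains no samples", from, to)
  i0 <- which(keep)[1L]
  time_series(x$values[keep], x$fs, t0 = tt[i0])
}

#' Read a time series from a plain-text file
#'
#' Accepts either one numeric value per line, or two comma/whitespace
#' separated columns `time,value`. Two-column input must be uniformly
#' sampled (relative spacing tolerance 1e-6); the rate is then inferred
#' from the time column and checked against `fs` if both are given.
#'
#' @param path file path.
#' @param fs sampling rate in Hz; required for one-column input.
#' @return a `loco_ts`.
#' @export
read_timeseries <- function(path, fs = NULL) {
  if (!file.exists(path)) stop_io("no such file: %s", path)
  first <- readLines(path, n = 1L)
  two_col <- grepl("[,\t ]", trimws(first))
  if (two_col) {
    tab <- utils::read.table(path, header = FALSE, sep = if (grepl(",", first)) "," else "")
    if (ncol(tab) != 2L) stop_format("expected 1 or 2 columns, got %d", ncol(tab))
    tt <- as.numeric(tab[[1L]]); vv <- as.numeric(tab[[2L]])
    if (anyNA(vv) || any(!is.finite(vv))) stop_validation("non-finite values in %s", path)
    dt <- diff(tt)
    if (length(dt) < 1L) stop_format("two-column input needs >= 2 rows")
    if (any(dt <= 0) || max(abs(dt - mean(dt))) > 1e-6 * mean(dt))
      stop_format("time column of %s is not uniformly spaced", path)
    fs_file <- 1 / mean(dt)
    if (!is.null(fs) && abs(fs - fs_file) > 1e-6 * fs_file)
      stop_format("declared fs (%g) disagrees with time column (%g)", fs, fs_file)
    return(time_series(vv, fs_file, t0 = tt[1L]))
  }
  if (is.null(fs)) stop_parameter("fs is required for one-column input")
  vv <- scan(path, what = double(), quiet = TRUE)
  if (anyNA(vv) || any(!is.finite(vv))) stop_validation("non-finite values in %s", path)
  time_series(vv, fs)
}

#' Write a time series as plain text (one value per line)
#'
#' Values are written with 17 significant digits so a write/read round trip
#' reproduces IEEE doubles exactly.
#'
#' @param x a `loco_ts`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(inherits(x, "loco_ts"))
  ok <- tryCatch({
    writeLines(sprintf("%.17g", x$values), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io("cannot write %s", path)
  invisible(path)
}
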