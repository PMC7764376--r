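#' Uniformly sampled time series
#'
#' Lightweight container used for every signal in the package: a numeric
#' sample vector, a sampling rate in Hz and the time of the first sample.
#' All PPG and volume traces, model outputs and filtered signals are
#' `time_series` objects.
#'
#' @param samples Numeric vector of finite sample values.
#' @param rate Sampling rate in samples per second (> 0).
#' @param t0 Time of the first sample, in seconds.
#'
#' @return An object of class `time_series` with elements `samples`,
#'   `rate` and `t0`.
#' @export
#'
#' @examples
#' ts <- time_series(sin(2 * pi * 0.2 * (0:249) / 25), rate = 25)
#' ts_duration(ts)
time_series <- function(samples, rate, t0 = 0) {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number")
  if (length(samples) == 0L)
    stop("'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("'samples' must be finite")
  structure(list(samples = samples, rate = rate, t0 = as.numeric(t0)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
              length(x$samples), x$rate, x$t0, ts_duration(x)))
  invisible(x)
}

#' @export
length.time_series <- function(x) length(x$samples)

#' Sample times of a time series
#'
#' @param ts A `time_series`.
#' @return Numeric vector of sample times in seconds.
#' @export
ts_time <- function(ts) {
  stopifnot(inherits(ts, "time_series"))
  ts$t0 + (seq_along(ts$samples) - 1) / ts$rate
}

#' Duration covered by a time series
#'
#' Duration is counted as n/rate, i.e. each sample owns one sample period.
#'
#' @param ts A `time_series`.
#' @return Duration in seconds.
#' @export
ts_duration <- function(ts) length(ts$samples) / ts$rate

#' Extract a time slice of a time series
#'
#' @param ts A `time_series`.
#' @param from,to Slice boundaries in seconds (inclusive of `from`,
#'   exclusive of `to`).
#' @return A `time_series` covering `[from, to)`.
#' @export
ts_slice <- function(ts, from, to) {
  stopifnot(inherits(ts, "time_series"), to > from)
  tt <- ts_time(ts)
  keep <- which(tt >= from - 1e-9 & tt < to - 1e-9)
  if (length(keep) == 0L) stop("slice contains no samples")
  time_series(ts$samples[keep], ts$rate, t0 = tt[keep[1]])
}
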