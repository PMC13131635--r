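#' Uniformly sampled time series
#'
#' Light container used throughout the package for LFP, clamp-current,
#' membrane-voltage and fluorescence signals: a numeric matrix (time in rows,
#' channels in columns) plus the sample rate, physical units and a channel
#' role tag.
#'
#' @param x numeric vector or matrix (rows = samples, columns = channels).
#' @param fs sample rate in Hz.
#' @param units physical units of the samples (e.g. "pA", "uV", "mV", "dFF").
#' @param role one of "lfp", "current", "voltage", "fluorescence", "signal".
#' @param t0 time of the first sample in ms (default 0).
#' @return an object of class `ts_sig`.
#' @export
timeseries <- function(x, fs, units = "a.u.", role = "signal", t0 = 0) {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stopf("fs must be a positive scalar (Hz)")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  structure(list(data = x, fs = fs, units = units, role = role, t0 = t0),
            class = "ts_sig")
}

#' @export
print.ts_sig <- function(x, ...) {
  cat(sprintf("<ts_sig> %d samples x %d channel(s), %g Hz, %.3f s, units=%s, role=%s\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs, x$units, x$role))
  invisible(x)
}

#' @export
plot.ts_sig <- function(x, channel = 1, ...) {
  t <- ts_time(x) / 1000
  graphics::plot(t, x$data[, channel], type = "l", xlab = "time (s)",
                 ylab = sprintf("%s (%s)", x$role, x$units), ...)
  invisible(x)
}

#' @export
length.ts_sig <- function(x) nrow(x$data)

#' Sample times of a time series in milliseconds
#' @param x a `ts_sig`.
#' @return numeric vector of sample times (ms).
#' @export
ts_time <- function(x) x$t0 + (seq_len(nrow(x$data)) - 1) * 1000 / x$fs

ts_values <- function(x, channel = 1) {
  if (inherits(x, "ts_sig")) x$data[, channel] else as.numeric(x)
}
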