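#' A uniformly sampled single-lead ECG trace
#'
#' The basic container the whole pipeline passes around: a numeric vector of
#' voltages in millivolts plus the sampling rate. Sample indices are 1-based
#' (the R convention) and time is `t = (index - 1) / fs` seconds.
#'
#' @param samples numeric vector of voltages (mV); must be finite, length >= 1.
#' @param fs sampling rate (Hz), > 0.
#' @param channel text label of the lead/channel.
#' @param source free-text provenance (file path, "synthetic", ...).
#' @return An object of class `ecg_signal`.
#' @export
#' @examples
#' s <- ecg_signal(sin(2 * pi * 1 * (0:719) / 360), fs = 360)
#' duration(s)
ecg_signal <- function(samples, fs, channel = "ECG", source = "unknown") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must have length >= 1", call. = FALSE)
  if (!all(is.finite(samples))) {
    stop("signal samples must be finite", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("fs must be a single positive number", call. = FALSE)
  }
  structure(list(samples = samples, fs = as.numeric(fs),
                 channel = as.character(channel),
                 source = as.character(source)),
            class = "ecg_signal")
}

#' @rdname ecg_signal
#' @param x an `ecg_signal`.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "ecg_signal"))
  length(x$samples) / x$fs
}

#' @export
length.ecg_signal <- function(x) length(x$samples)

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal> %s: %d samples @ %g Hz (%.2f s), %.3f..%.3f mV [%s]\n",
              x$channel, length(x$samples), x$fs, duration(x),
              min(x$samples), max(x$samples), x$source))
  invisible(x)
}

#' @export
plot.ecg_signal <- function(x, from = 0, to = min(duration(x), 10), ...) {
  i <- seq.int(floor(from * x$fs) + 1L, min(length(x$samples), ceiling(to * x$fs)))
  t <- (i - 1) / x$fs
  plot(t, x$samples[i], type = "l", xlab = "time (s)", ylab = "mV",
       main = x$channel, ...)
  invisible(x)
}

# internal: time vector of a signal
signal_times <- function(x) (seq_along(x$samples) - 1) / x$fs
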