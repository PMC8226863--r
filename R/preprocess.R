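#' Frequency-domain conditioning specification
#'
#' The acquisition chain band-limits the ECG to 0.5--40 Hz and suppresses
#' noise in the frequency domain: after band limiting, spectral bins whose
#' magnitude falls below `rel_threshold` times the maximum in-band magnitude
#' are treated as noise and zeroed (default threshold 0.2).
#'
#' @param low_hz lower band edge (Hz); bins strictly below it are removed,
#'   including DC.
#' @param high_hz upper band edge (Hz); bins strictly above it are removed.
#' @param rel_threshold fraction of the maximum in-band magnitude below which
#'   a bin is zeroed by [fft_threshold_denoise()]; in `[0, 1)`.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.5, high_hz = 40, rel_threshold = 0.2) {
  if (low_hz < 0 || high_hz <= low_hz) {
    stop("need 0 <= low_hz < high_hz", call. = FALSE)
  }
  if (rel_threshold < 0 || rel_threshold >= 1) {
    stop("rel_threshold must be in [0, 1)", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 rel_threshold = rel_threshold),
            class = "filter_spec")
}

#' Band-limit a signal by zeroing out-of-band FFT bins
#'
#' Transforms the signal with the discrete Fourier transform, zeroes every
#' bin whose frequency lies below `low_hz` (including DC) or above `high_hz`,
#' and inverse-transforms. Because bins are only zeroed (conjugate-symmetric
#' pairs together), the output is real, has the same length and sampling
#' rate, and its energy never exceeds the input's (Parseval).
#'
#' @param signal an [ecg_signal].
#' @param spec a [filter_spec()]; `rel_threshold` is ignored here.
#' @return A new [ecg_signal].
#' @export
#' @examples
#' fs <- 360
#' x <- ecg_signal(sin(2 * pi * 10 * (0:(fs - 1)) / fs), fs)
#' y <- bandlimit(x, filter_spec(0.5, 40))
#' cor(x$samples, y$samples)  # ~1: 10 Hz is in band
bandlimit <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(spec, "filter_spec"))
  if (length(signal$samples) < 2L) {
    stop("signal must have length >= 2", call. = FALSE)
  }
  if (spec$high_hz >= signal$fs / 2) {
    stop("high_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  X <- stats::fft(signal$samples)
  keep <- in_band_mask(length(X), signal$fs, spec$low_hz, spec$high_hz)
  X[!keep] <- 0+0i
  y <- Re(stats::fft(X, inverse = TRUE)) / length(X)
  ecg_signal(y, signal$fs, signal$channel,
             source = paste0(signal$source, "|bandlimit"))
}

#' Magnitude-threshold denoising in the frequency domain
#'
#' After band limiting to `[low_hz, high_hz]`, the maximum in-band spectral
#' magnitude is found (DC excluded) and every bin whose magnitude is below
#' `rel_threshold` times that maximum is zeroed as noise; the inverse
#' transform reconstructs the signal. An all-zero signal is returned
#' unchanged. Bins are zeroed in conjugate pairs so the output is real.
#'
#' @inheritParams bandlimit
#' @return A new [ecg_signal] with `sum(y^2) <= sum(x^2)`.
#' @export
fft_threshold_denoise <- function(signal, spec = filter_spec()) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(spec, "filter_spec"))
  if (length(signal$samples) < 2L) {
    stop("signal must have length >= 2", call. = FALSE)
  }
  if (spec$high_hz >= signal$fs / 2) {
    stop("high_hz must be below the Nyquist frequency fs/2", call. = FALSE)
  }
  if (all(signal$samples == 0)) return(signal)
  X <- stats::fft(signal$samples)
  keep <- in_band_mask(length(X), signal$fs, spec$low_hz, spec$high_hz)
  X[!keep] <- 0+0i
  mx <- max(Mod(X[keep]))
  if (mx > 0 && spec$rel_threshold > 0) {
    X[Mod(X) < spec$rel_threshold * mx] <- 0+0i
  }
  y <- Re(stats::fft(X, inverse = TRUE)) / length(X)
  ecg_signal(y, signal$fs, signal$channel,
             source = paste0(signal$source, "|denoise"))
}

# Logical mask over DFT bins whose absolute frequency lies in [low, high].
# Bin k (0-based) has frequency min(k, n - k) * fs / n, so conjugate pairs
# share a frequency and are kept or dropped together.
in_band_mask <- function(n, fs, low, high) {
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  f >= low & f <= high & k != 0L
}
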