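#' Generate a synthetic single-lead ECG recording with ground truth
#'
#' Synthesises a recording of one morphology class by placing beat templates
#' (sums of Gaussian P/Q/R/S/T bumps, see [class_template()]) at programmed R
#' times. The mean RR interval is `60 / heart_rate_bpm` seconds with optional
#' Gaussian jitter (truncated at +/-20% of RR). The returned object carries
#' the exact programmed R-peak sample indices and per-beat labels, so every
#' downstream stage (detection, segmentation, classification) can be scored
#' against ground truth without any external data.
#'
#' Identical arguments produce bit-identical output; the generator uses its
#' own RNG stream and leaves the caller's RNG state untouched.
#'
#' @param cls morphology class, one of [beat_classes()].
#' @param duration_s recording length in seconds (must exceed two beats).
#' @param fs sampling rate in Hz (>= 100; the reference database uses 360).
#' @param heart_rate_bpm mean heart rate, 20--220 bpm (the device targets
#'   resting rates of 60--100 bpm).
#' @param noise optional [noise_spec()]; `NULL` for a clean recording.
#' @param rr_jitter_frac sd of the RR jitter as a fraction of RR (default
#'   0.03; 0 gives perfectly periodic beats).
#' @param seed integer seed controlling jitter and noise.
#' @return An object of class `synthetic_recording`: list with `signal`
#'   ([ecg_signal]), `true_r_peaks` (1-based sample indices, ascending),
#'   `beat_labels` (character, one per peak) and `seed`.
#' @export
#' @examples
#' rec <- generate_recording("SINUS_RHYTHM", duration_s = 10, fs = 360,
#'                           heart_rate_bpm = 60, rr_jitter_frac = 0, seed = 1)
#' length(rec$true_r_peaks)  # 10 beats
generate_recording <- function(cls, duration_s, fs = 360,
                               heart_rate_bpm = 75, noise = NULL,
                               rr_jitter_frac = 0.03, seed = 1L) {
  cls <- as_beat_class(cls)
  stopifnot(length(cls) == 1L)
  if (heart_rate_bpm < 20 || heart_rate_bpm > 220) {
    stop("heart_rate_bpm must be within 20..220", call. = FALSE)
  }
  if (fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  rr <- 60 / heart_rate_bpm
  if (duration_s <= 2 * rr) {
    stop("duration_s must exceed two beats", call. = FALSE)
  }
  if (rr_jitter_frac < 0) stop("rr_jitter_frac must be >= 0", call. = FALSE)

  params <- class_template(cls)

  out <- with_local_seed(seed, {
    # programmed R times: first beat half an RR in, then jittered steps
    r_times <- numeric(0)
    t_next <- rr / 2
    while (t_next <= duration_s - rr / 2 + 1e-9) {
      r_times <- c(r_times, t_next)
      eps <- if (rr_jitter_frac > 0) {
        e <- stats::rnorm(1, 0, rr_jitter_frac)
        max(-0.2, min(0.2, e))
      } else 0
      t_next <- t_next + rr * (1 + eps)
    }
    n <- round(duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    v <- numeric(n)
    for (k in seq_along(r_times)) {
      # local RR (for P/T/ST stretch): interval following this beat
      rr_loc <- if (k < length(r_times)) r_times[k + 1] - r_times[k]
                else if (k > 1) r_times[k] - r_times[k - 1] else rr
      rel <- t - r_times[k]
      # only evaluate the template near the beat
      win <- which(rel > -0.6 * rr_loc & rel < 0.9 * rr_loc)
      v[win] <- v[win] + beat_waveform(params, rel[win], rr_scale = rr_loc)
    }
    sig <- ecg_signal(v, fs, channel = "synthetic",
                      source = sprintf("synthetic:%s:seed=%d", cls, seed))
    if (!is.null(noise)) sig <- add_noise_spec(sig, noise, seed = seed + 1L)
    list(signal = sig, r_times = r_times)
  })

  peaks <- as.integer(round(out$r_times * fs)) + 1L
  structure(list(signal = out$signal,
                 true_r_peaks = peaks,
                 beat_labels = rep(cls, length(peaks)),
                 seed = as.integer(seed)),
            class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  cat(sprintf("<synthetic_recording> %s: %d beats, %.1f s @ %g Hz (seed %d)\n",
              x$beat_labels[1], length(x$true_r_peaks), duration(x$signal),
              x$signal$fs, x$seed))
  invisible(x)
}

#' Noise specification for synthetic recordings
#'
#' Additive disturbances that emulate what a chest-lead prototype picks up:
#' sinusoidal baseline wander (respiration-band drift), sinusoidal powerline
#' interference, and white Gaussian sensor noise.
#'
#' @param baseline_amp amplitude of baseline wander (mV).
#' @param baseline_hz baseline wander frequency (Hz; respiration ~0.25 Hz).
#' @param powerline_amp amplitude of mains interference (mV).
#' @param powerline_hz mains frequency (Hz; 50 or 60).
#' @param white_sd standard deviation of white noise (mV).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0, baseline_hz = 0.25,
                       powerline_amp = 0, powerline_hz = 60,
                       white_sd = 0) {
  if (baseline_amp < 0 || powerline_amp < 0 || white_sd < 0) {
    stop("noise amplitudes must be >= 0", call. = FALSE)
  }
  structure(list(baseline_amp = baseline_amp, baseline_hz = baseline_hz,
                 powerline_amp = powerline_amp, powerline_hz = powerline_hz,
                 white_sd = white_sd),
            class = "noise_spec")
}

#' Add synthetic noise to an ECG signal
#'
#' Adds a sinusoid at the baseline-wander frequency, a sinusoid at the mains
#' frequency, and white Gaussian noise. With all amplitudes zero the signal
#' is returned unchanged. Length and sampling rate are preserved.
#'
#' @param signal an [ecg_signal].
#' @param baseline_amp,baseline_hz,powerline_amp,powerline_hz,white_sd see
#'   [noise_spec()].
#' @param seed integer seed for the white-noise component.
#' @return A new [ecg_signal].
#' @export
add_noise <- function(signal, baseline_amp = 0, baseline_hz = 0.25,
                      powerline_amp = 0, powerline_hz = 60,
                      white_sd = 0, seed = 1L) {
  add_noise_spec(signal,
                 noise_spec(baseline_amp, baseline_hz,
                            powerline_amp, powerline_hz, white_sd),
                 seed = seed)
}

#' @rdname add_noise
#' @param spec a [noise_spec()].
#' @export
add_noise_spec <- function(signal, spec, seed = 1L) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(spec, "noise_spec"))
  t <- signal_times(signal)
  v <- signal$samples
  if (spec$baseline_amp > 0) {
    v <- v + spec$baseline_amp * sin(2 * pi * spec$baseline_hz * t)
  }
  if (spec$powerline_amp > 0) {
    v <- v + spec$powerline_amp * sin(2 * pi * spec$powerline_hz * t)
  }
  if (spec$white_sd > 0) {
    v <- v + with_local_seed(seed, stats::rnorm(length(v), 0, spec$white_sd))
  }
  ecg_signal(v, signal$fs, signal$channel,
             source = paste0(signal$source, "+noise"))
}

#' Write / read the ground truth of a synthetic recording
#'
#' The signal goes to CSV via [write_ecg_csv()]; peaks, labels and seed go to
#' a JSON sidecar so a recording can be reloaded with its ground truth.
#'
#' @param rec a `synthetic_recording`.
#' @param csv_path path for the signal CSV.
#' @param json_path path for the ground-truth sidecar (default: csv path with
#'   `.json` extension).
#' @return `csv_path`, invisibly.
#' @export
write_recording <- function(rec, csv_path,
                            json_path = sub("\\.[^.]*$", ".json", csv_path)) {
  stopifnot(inherits(rec, "synthetic_recording"))
  write_ecg_csv(rec$signal, csv_path)
  jsonlite::write_json(
    list(peaks = rec$true_r_peaks, labels = rec$beat_labels, seed = rec$seed),
    json_path, auto_unbox = TRUE)
  invisible(csv_path)
}

#' @rdname write_recording
#' @export
read_recording <- function(csv_path,
                           json_path = sub("\\.[^.]*$", ".json", csv_path)) {
  sig <- read_ecg_csv(csv_path)
  gt <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(signal = sig,
                 true_r_peaks = as.integer(gt$peaks),
                 beat_labels = as.character(gt$labels),
                 seed = as.integer(gt$seed)),
            class = "synthetic_recording")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(as.numeric(seed) %% 2147483647))
  expr
}
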