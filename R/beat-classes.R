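#' The four beat morphology classes
#'
#' The classifier distinguishes four single-beat morphologies: QRS widening
#' (abnormally long ventricular depolarisation, conventionally >= 120 ms),
#' normal sinus rhythm, ST-segment depression and ST-segment elevation
#' (downward / upward displacement of the baseline stretch between the S and
#' T waves, the classic ischemia / infarction markers).
#'
#' Classes carry stable integer codes 0--3 in the order listed, so that
#' confusion tables and on-disk manifests are unambiguous across runs.
#'
#' @return Character vector of the four class names, in code order.
#' @export
#' @examples
#' beat_classes()
#' beat_class_code("SINUS_RHYTHM")
beat_classes <- function() {
  c("QRS_WIDENING", "SINUS_RHYTHM", "ST_DEPRESSION", "ST_ELEVATION")
}

#' @rdname beat_classes
#' @param cls character; one of `beat_classes()`.
#' @export
beat_class_code <- function(cls) {
  cls <- as_beat_class(cls)
  match(cls, beat_classes()) - 1L
}

#' @rdname beat_classes
#' @param x character vector of putative class names.
#' @export
as_beat_class <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), beat_classes())
  if (length(bad) > 0L) {
    stop("unknown beat class: ", paste(bad, collapse = ", "),
         " (valid: ", paste(beat_classes(), collapse = ", "), ")",
         call. = FALSE)
  }
  x
}

#' @rdname beat_classes
#' @export
beat_class_factor <- function(x) {
  factor(as_beat_class(x), levels = beat_classes())
}

#' Morphology parameters of one beat template
#'
#' A beat is modelled as a sum of five Gaussian bumps (P, Q, R, S, T waves)
#' plus a plateau offset over the ST segment. Each wave has an amplitude in
#' mV, a centre offset from the R peak in seconds, and a Gaussian width
#' (standard deviation) in seconds.
#'
#' @param waves data.frame with columns `wave` (P,Q,R,S,T), `amp` (mV),
#'   `center` (s, offset from R), `width` (s, Gaussian sd).
#' @param st_offset mV; baseline shift applied between the end of the S wave
#'   and the onset of the T wave (0 for a normal beat).
#' @param qrs_width_scale dimensionless >= 1; widens the QRS complex by
#'   scaling the Q, R, S centres and widths.
#' @return An object of class `morphology_params`.
#' @export
morphology_params <- function(waves, st_offset = 0, qrs_width_scale = 1) {
  stopifnot(is.data.frame(waves),
            all(c("wave", "amp", "center", "width") %in% names(waves)))
  waves <- waves[match(c("P", "Q", "R", "S", "T"), waves$wave), , drop = FALSE]
  if (anyNA(waves$wave)) {
    stop("waves must contain exactly P, Q, R, S, T", call. = FALSE)
  }
  if (waves$amp[waves$wave == "R"] <= 0) {
    stop("R amplitude must be positive", call. = FALSE)
  }
  if (any(waves$width <= 0)) stop("wave widths must be positive", call. = FALSE)
  if (any(diff(waves$center) <= 0)) {
    stop("wave centers must be strictly ordered P < Q < R < S < T",
         call. = FALSE)
  }
  if (qrs_width_scale < 1) stop("qrs_width_scale must be >= 1", call. = FALSE)
  structure(list(waves = waves, st_offset = st_offset,
                 qrs_width_scale = qrs_width_scale),
            class = "morphology_params")
}

# Base sinus wave table. Numbers are package conventions (mV / s), chosen so
# the QRS duration measured at 10% of the R amplitude is ~90 ms.
.sinus_waves <- function() {
  data.frame(
    wave   = c("P", "Q", "R", "S", "T"),
    amp    = c(0.15, -0.12, 1.00, -0.22, 0.30),
    center = c(-0.170, -0.034, 0.000, 0.034, 0.260),
    width  = c(0.025, 0.013, 0.013, 0.013, 0.055)
  )
}

#' Deterministic beat template for a morphology class
#'
#' Returns the per-wave Gaussian parameters that define the canonical beat of
#' each class: sinus rhythm has a ~90 ms QRS and no ST shift; QRS widening
#' scales the QRS complex so its duration (at 10% of the R amplitude) exceeds
#' 120 ms; ST depression / elevation shift the ST plateau by -0.15 / +0.20 mV.
#'
#' @param cls one of `beat_classes()`.
#' @return A [morphology_params] object.
#' @export
#' @examples
#' class_template("ST_ELEVATION")$st_offset
class_template <- function(cls) {
  cls <- as_beat_class(cls)
  stopifnot(length(cls) == 1L)
  switch(cls,
    SINUS_RHYTHM  = morphology_params(.sinus_waves(), st_offset = 0),
    QRS_WIDENING  = morphology_params(.sinus_waves(), st_offset = 0,
                                      qrs_width_scale = 1.5),
    ST_DEPRESSION = morphology_params(.sinus_waves(), st_offset = -0.15),
    ST_ELEVATION  = morphology_params(.sinus_waves(), st_offset = 0.20)
  )
}

#' Evaluate a beat template at times relative to the R peak
#'
#' Sums the five Gaussian waves (Q, R, S scaled by `qrs_width_scale`) and
#' adds the ST plateau, a raised-cosine-edged shelf between the end of the S
#' wave and the onset of the T wave. When `rr_scale != 1` the P and T wave
#' centres and the ST plateau stretch linearly with the local RR interval,
#' while the QRS complex keeps its absolute duration, mirroring how diastole
#' absorbs most rate variation.
#'
#' @param params a [morphology_params] object.
#' @param t numeric vector of times (s) relative to the R peak.
#' @param rr_scale local RR interval divided by 1 s (the 60 bpm reference).
#' @return Numeric vector of voltages (mV).
#' @export
beat_waveform <- function(params, t, rr_scale = 1) {
  stopifnot(inherits(params, "morphology_params"), rr_scale > 0)
  w <- params$waves
  qs <- params$qrs_width_scale
  v <- numeric(length(t))
  for (i in seq_len(nrow(w))) {
    ctr <- w$center[i]
    wid <- w$width[i]
    if (w$wave[i] %in% c("Q", "R", "S")) {
      ctr <- ctr * qs
      wid <- wid * qs
    } else {
      ctr <- ctr * rr_scale
    }
    v <- v + w$amp[i] * exp(-(t - ctr)^2 / (2 * wid^2))
  }
  if (params$st_offset != 0) {
    s_end   <- (w$center[w$wave == "S"] * qs + 2 * w$width[w$wave == "S"] * qs)
    t_onset <- (w$center[w$wave == "T"] - 2 * w$width[w$wave == "T"]) * rr_scale
    v <- v + params$st_offset * .plateau(t, s_end, t_onset, ramp = 0.02)
  }
  v
}

# Smooth shelf: 0 outside [lo - ramp, hi + ramp], 1 on [lo, hi], raised-cosine
# edges of width `ramp`.
.plateau <- function(t, lo, hi, ramp = 0.02) {
  if (hi <= lo) return(numeric(length(t)))
  p <- numeric(length(t))
  core <- t >= lo & t <= hi
  p[core] <- 1
  up <- t > lo - ramp & t < lo
  p[up] <- 0.5 * (1 + cos(pi * (lo - t[up]) / ramp))
  dn <- t > hi & t < hi + ramp
  p[dn] <- 0.5 * (1 + cos(pi * (t[dn] - hi) / ramp))
  p
}

#' QRS duration of a template, measured at 10% of the R amplitude
#'
#' Renders the Q, R and S waves alone on a fine grid and measures the span of
#' the region where the absolute voltage exceeds 10% of the R amplitude.
#'
#' @param params a [morphology_params] object.
#' @param fs sampling rate of the measurement grid (Hz).
#' @return Duration in seconds.
#' @export
qrs_duration <- function(params, fs = 2000) {
  stopifnot(inherits(params, "morphology_params"))
  w <- params$waves
  qs <- params$qrs_width_scale
  span <- 0.25 * qs
  t <- seq(-span, span, by = 1 / fs)
  v <- numeric(length(t))
  for (i in which(w$wave %in% c("Q", "R", "S"))) {
    v <- v + w$amp[i] *
      exp(-(t - w$center[i] * qs)^2 / (2 * (w$width[i] * qs)^2))
  }
  r_amp <- w$amp[w$wave == "R"]
  idx <- which(abs(v) >= 0.1 * r_amp)
  (t[max(idx)] - t[min(idx)])
}

#' ST analysis window for a beat
#'
#' The ST segment is measured over \[R + 0.06 s, R + 0.20 s\] at 60 bpm,
#' scaled linearly with the local RR interval.
#'
#' @param rr_scale local RR interval / 1 s.
#' @return Numeric length-2 vector: window start and end (s, relative to R).
#' @export
st_window <- function(rr_scale = 1) c(0.06, 0.20) * rr_scale
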