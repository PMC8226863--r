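#' Detect R peaks in a single-lead ECG
#'
#' A Pan--Tompkins-style detector: band-pass the signal to the QRS band
#' (5--15 Hz, Butterworth, zero-phase), differentiate, square, integrate over
#' a 150 ms moving window, threshold the integrated energy adaptively
#' (mean + `k` standard deviations over a sliding 2 s window), enforce a
#' refractory period, and finally snap each candidate to the local maximum of
#' the raw signal within +/-50 ms.
#'
#' A flat (zero-variance) signal yields an empty peak list rather than an
#' error.
#'
#' @param signal an [ecg_signal]; duration >= 2 s, fs >= 100 Hz.
#' @param k adaptive-threshold multiplier on the rolling standard deviation.
#' @param refractory_s minimum spacing between peaks (s).
#' @param snap_s half-width of the raw-maximum snap window (s).
#' @return An object of class `rpeak_list`: list with `indices` (1-based,
#'   strictly ascending) and `fs`.
#' @export
#' @examples
#' rec <- generate_recording("SINUS_RHYTHM", 10, 360, 60,
#'                           rr_jitter_frac = 0, seed = 1)
#' detect_r_peaks(rec$signal)$indices
#' rec$true_r_peaks
detect_r_peaks <- function(signal, k = 1.5, refractory_s = 0.2,
                           snap_s = 0.05) {
  stopifnot(inherits(signal, "ecg_signal"))
  if (duration(signal) < 2) stop("signal duration must be >= 2 s", call. = FALSE)
  if (signal$fs < 100) stop("fs must be >= 100 Hz", call. = FALSE)
  x <- signal$samples
  fs <- signal$fs
  if (stats::sd(x) == 0) return(rpeak_list(integer(0), fs))

  # QRS-band energy
  bp <- signal::butter(2, c(5, 15) / (fs / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  d <- c(0, diff(xf))
  sq <- d^2
  w <- max(1L, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0

  # adaptive threshold over a sliding 2 s window
  thr <- rolling_mean_sd_threshold(integ, win = round(2 * fs), k = k)
  above <- integ > thr
  if (!any(above)) return(rpeak_list(integer(0), fs))

  # one candidate per contiguous supra-threshold region
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  regions <- which(r$values)
  cand <- vapply(regions, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    i0 + which.max(integ[i0:i1]) - 1L
  }, integer(1))

  # refractory: greedy keep-the-stronger within refractory_s
  cand <- cand[order(cand)]
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  for (c0 in cand) {
    if (length(keep) == 0L || c0 - keep[length(keep)] >= refr) {
      keep <- c(keep, c0)
    } else if (integ[c0] > integ[keep[length(keep)]]) {
      keep[length(keep)] <- c0
    }
  }

  # snap to the raw local maximum within +/- snap_s
  half <- as.integer(round(snap_s * fs))
  peaks <- vapply(keep, function(c0) {
    i0 <- max(1L, c0 - half)
    i1 <- min(length(x), c0 + half)
    i0 + which.max(x[i0:i1]) - 1L
  }, integer(1))
  peaks <- unique(peaks)

  # snapping can collapse spacing below the refractory period; re-enforce
  if (length(peaks) > 1L) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
      else if (x[p] > x[out[length(out)]]) out[length(out)] <- p
    }
    peaks <- out
  }
  rpeak_list(peaks, fs)
}

#' @rdname detect_r_peaks
#' @param indices 1-based sample indices, strictly ascending.
#' @param fs sampling rate (Hz).
#' @export
rpeak_list <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  structure(list(indices = indices, fs = as.numeric(fs)),
            class = "rpeak_list")
}

#' @export
print.rpeak_list <- function(x, ...) {
  cat(sprintf("<rpeak_list> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' RR intervals from an R-peak list
#'
#' `n` peaks yield `n - 1` intervals, `diff(indices) / fs` seconds.
#'
#' @param peaks an [rpeak_list()] (or a `synthetic_recording`, whose ground
#'   truth peaks are used).
#' @return Numeric vector of RR intervals in seconds.
#' @export
rr_intervals <- function(peaks) {
  if (inherits(peaks, "synthetic_recording")) {
    peaks <- rpeak_list(peaks$true_r_peaks, peaks$signal$fs)
  }
  stopifnot(inherits(peaks, "rpeak_list"))
  if (length(peaks$indices) < 2L) {
    stop("need at least 2 peaks to compute RR intervals", call. = FALSE)
  }
  diff(peaks$indices) / peaks$fs
}

#' Cut beats as half-RR windows around interior R peaks
#'
#' For each interior peak `R_i` the segment spans the half RR interval before
#' and after it: samples `[R_i - floor(RR_prev/2), R_i + floor(RR_next/2))`
#' (half-open, so adjacent segments never overlap). The first and last peaks
#' lack a neighbour on one side and produce no segment.
#'
#' @param signal an [ecg_signal].
#' @param peaks an [rpeak_list()] with >= 3 peaks.
#' @param labels optional character vector (one per peak) of beat classes.
#' @return List of `beat_segment` objects: `samples` (mV), `fs`,
#'   `r_index_local`, `r_index_global`, `label` (or `NA`).
#' @export
segment_beats <- function(signal, peaks, labels = NULL) {
  stopifnot(inherits(signal, "ecg_signal"), inherits(peaks, "rpeak_list"))
  idx <- peaks$indices
  if (length(idx) < 3L) {
    stop("need at least 3 peaks (interior beats require both neighbours)",
         call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(idx)) {
    stop("labels must have one entry per peak", call. = FALSE)
  }
  n <- length(signal$samples)
  segs <- vector("list", length(idx) - 2L)
  for (j in 2:(length(idx) - 1L)) {
    half_prev <- (idx[j] - idx[j - 1]) %/% 2L
    half_next <- (idx[j + 1] - idx[j]) %/% 2L
    i0 <- max(1L, idx[j] - half_prev)
    i1 <- min(n, idx[j] + half_next - 1L)   # half-open upper bound
    segs[[j - 1L]] <- structure(
      list(samples = signal$samples[i0:i1], fs = signal$fs,
           r_index_local = idx[j] - i0 + 1L, r_index_global = idx[j],
           label = if (is.null(labels)) NA_character_ else labels[j]),
      class = "beat_segment")
  }
  segs
}

#' @export
print.beat_segment <- function(x, ...) {
  cat(sprintf("<beat_segment> %d samples @ %g Hz, R at %d (global %d)%s\n",
              length(x$samples), x$fs, x$r_index_local, x$r_index_global,
              if (is.na(x$label)) "" else paste0(", label ", x$label)))
  invisible(x)
}

#' Match detected peaks against ground truth
#'
#' Greedy one-to-one matching within a time tolerance; reports sensitivity
#' (matched truth / truth), positive predictivity (matched detections /
#' detections) and the matched pairs.
#'
#' @param detected an [rpeak_list()].
#' @param truth integer vector of true peak indices (1-based).
#' @param tol_s matching tolerance in seconds (default 0.025 = 25 ms).
#' @return List with `n_truth`, `n_detected`, `n_matched`, `sensitivity`,
#'   `ppv`, and `matched` (data.frame truth/detected indices).
#' @export
match_peaks <- function(detected, truth, tol_s = 0.025) {
  stopifnot(inherits(detected, "rpeak_list"))
  tol <- tol_s * detected$fs
  det <- detected$indices
  used <- logical(length(det))
  mt <- integer(0); md <- integer(0)
  for (tr in truth) {
    dif <- abs(det - tr)
    dif[used] <- Inf
    j <- which.min(dif)
    if (length(j) == 1L && is.finite(dif[j]) && dif[j] <= tol) {
      used[j] <- TRUE
      mt <- c(mt, tr); md <- c(md, det[j])
    }
  }
  list(n_truth = length(truth), n_detected = length(det),
       n_matched = length(mt),
       sensitivity = if (length(truth)) length(mt) / length(truth) else NA_real_,
       ppv = if (length(det)) length(mt) / length(det) else NA_real_,
       matched = data.frame(truth = mt, detected = md))
}

# threshold[i] = mean + k * sd of `v` over a centred window of `win` samples,
# computed with cumulative sums.
rolling_mean_sd_threshold <- function(v, win, k) {
  n <- length(v)
  win <- max(2L, min(win, n))
  half <- win %/% 2L
  cs <- cumsum(c(0, v))
  cs2 <- cumsum(c(0, v^2))
  i0 <- pmax(1L, seq_len(n) - half)
  i1 <- pmin(n, seq_len(n) + half)
  cnt <- i1 - i0 + 1L
  m <- (cs[i1 + 1L] - cs[i0]) / cnt
  vvar <- pmax(0, (cs2[i1 + 1L] - cs2[i0]) / cnt - m^2)
  m + k * sqrt(vvar)
}
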