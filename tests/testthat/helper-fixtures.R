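# Shared fixtures, built in code. Heavier objects are cached per session so
# several test files can reuse them without regenerating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# clean 10 s sinus recording at 60 bpm, no jitter
clean_sinus <- function() {
  cached("clean_sinus", function() {
    generate_recording("SINUS_RHYTHM", duration_s = 10, fs = 360,
                       heart_rate_bpm = 60, rr_jitter_frac = 0, seed = 1)
  })
}

# labeled beat segments, n per class, detector-segmented from clean
# band-limited synthetic recordings
synthetic_beats <- function(n_per_class, seed = 11, hr = 72) {
  beats <- list()
  for (cls in beat_classes()) {
    code <- beat_class_code(cls)
    rec <- generate_recording(cls, duration_s = (n_per_class + 5) * 60 / hr,
                              fs = 360, heart_rate_bpm = hr,
                              rr_jitter_frac = 0.03, seed = seed * 10 + code)
    sig <- bandlimit(rec$signal)
    pk <- detect_r_peaks(sig)
    segs <- segment_beats(sig, pk, labels = rep(cls, length(pk$indices)))
    stopifnot(length(segs) >= n_per_class)
    beats <- c(beats, segs[seq_len(n_per_class)])
  }
  beats
}

# small rendered image dataset manifest: 4 classes x n beats
synthetic_manifest <- function(n_per_class = 12, size = 48, seed = 11) {
  key <- sprintf("manifest_%d_%d_%d", n_per_class, size, seed)
  cached(key, function() {
    dir <- file.path(tempdir(), paste0("ecgflow_fix_", key))
    build_image_dataset(synthetic_beats(n_per_class, seed = seed), dir,
                        size = size)
  })
}

# the three published confusion tables shipped as package fixtures
paper_confusion <- function(model) {
  path <- system.file("extdata", paste0("confusion_", model, ".csv"),
                      package = "ecgflow")
  read_confusion_csv(path)
}

# brute-force Wilcoxon signed-rank two-sided p over all 2^n sign vectors
brute_force_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_ge <- mean(vs >= v_obs - 1e-9)
  p_le <- mean(vs <= v_obs + 1e-9)
  min(1, 2 * min(p_ge, p_le))
}

# fake manifest (labels only) for split/balance arithmetic
label_manifest <- function(counts) {
  data.frame(path = sprintf("img%06d.png", seq_len(sum(counts))),
             label = rep(beat_classes()[seq_along(counts)], counts),
             stringsAsFactors = FALSE)
}
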