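test_that("detector recovers every programmed peak on clean recordings", {
  rec <- clean_sinus()
  pk <- detect_r_peaks(rec$signal)
  m <- match_peaks(pk, rec$true_r_peaks, tol_s = 0.025)
  expect_equal(m$n_detected, length(rec$true_r_peaks))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 1)

  # all-zero and flat signals give an empty list, not an error
  expect_length(detect_r_peaks(ecg_signal(rep(0, 720), 360))$indices, 0L)
  expect_length(detect_r_peaks(ecg_signal(rep(2, 720), 360))$indices, 0L)

  expect_error(detect_r_peaks(ecg_signal(rep(0, 300), 360)), "duration")
})

test_that("detector stays reliable under white measurement noise", {
  rec <- generate_recording("SINUS_RHYTHM", 30, 360, 75, rr_jitter_frac = 0.03,
                            noise = noise_spec(white_sd = 0.05), seed = 13)
  m <- match_peaks(detect_r_peaks(rec$signal), rec$true_r_peaks)
  expect_gte(m$sensitivity, 0.95)
  expect_gte(m$ppv, 0.95)
})

test_that("rr_intervals is diff over fs with the n-1 length law", {
  pk <- rpeak_list(c(361L, 721L, 1081L), 360)
  expect_equal(rr_intervals(pk), c(1.0, 1.0))

  for (n in c(2, 5, 23)) {
    idx <- cumsum(c(100, sample(80:120, n - 1, replace = TRUE)))
    expect_length(rr_intervals(rpeak_list(idx, 360)), n - 1L)
  }
  expect_error(rr_intervals(rpeak_list(500L, 360)), "at least 2")
  expect_error(rpeak_list(c(100L, 90L), 360), "increasing")
})

test_that("segments cover half the RR interval on each side of R", {
  sig <- ecg_signal(seq_len(1500) * 0, 360)
  pk <- rpeak_list(c(361L, 721L, 1081L), 360)
  segs <- segment_beats(sig, pk)
  expect_length(segs, 1L)
  # half-RR window: samples 541..900, R at local position 181
  expect_length(segs[[1]]$samples, 360L)
  expect_equal(segs[[1]]$r_index_local, 181L)
  expect_equal(segs[[1]]$r_index_global, 721L)

  # 10 equally spaced peaks -> 8 interior segments, all identical length
  idx <- seq(361L, by = 360L, length.out = 10)
  sig2 <- ecg_signal(numeric(4200), 360)
  segs2 <- segment_beats(sig2, rpeak_list(idx, 360))
  expect_length(segs2, 8L)
  expect_true(all(vapply(segs2, function(s) length(s$samples), integer(1)) ==
                    360L))

  expect_error(segment_beats(sig, rpeak_list(c(361L, 721L), 360)),
               "at least 3")
})

test_that("uniform-RR segments tile the interior span without gaps", {
  idx <- seq(361L, by = 360L, length.out = 6)   # even RR in samples
  sig <- ecg_signal(numeric(2400), 360)
  segs <- segment_beats(sig, rpeak_list(idx, 360))
  starts <- vapply(segs, function(s) s$r_index_global - s$r_index_local + 1L,
                   integer(1))
  ends <- starts + vapply(segs, function(s) length(s$samples), integer(1)) - 1L
  expect_equal(starts[1], 361L + 180L)                    # midpoint(P1, P2)
  expect_equal(ends[length(ends)], idx[6] - 180L - 1L)    # midpoint(P5, P6) - 1
  expect_true(all(starts[-1] == ends[-length(ends)] + 1L))  # no gaps/overlap
})

test_that("detected RR matches programmed RR within 1% across resting rates", {
  for (hr in c(60, 80, 100)) {
    rec <- generate_recording("SINUS_RHYTHM", 30, 360, hr,
                              rr_jitter_frac = 0, seed = 21)
    pk <- detect_r_peaks(rec$signal)
    expect_equal(mean(rr_intervals(pk)), 60 / hr, tolerance = 0.01)
  }
})

test_that("segment labels follow their peaks", {
  rec <- clean_sinus()
  pk <- rpeak_list(rec$true_r_peaks, 360)
  segs <- segment_beats(rec$signal, pk, labels = rec$beat_labels)
  expect_true(all(vapply(segs, function(s) s$label, character(1)) ==
                    "SINUS_RHYTHM"))
  expect_error(segment_beats(rec$signal, pk, labels = "SINUS_RHYTHM"),
               "one entry per peak")
})
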