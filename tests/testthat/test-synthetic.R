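test_that("class templates encode the four morphologies", {
  expect_equal(class_template("SINUS_RHYTHM")$st_offset, 0)
  expect_lt(class_template("ST_DEPRESSION")$st_offset, -0.1 + 1e-12)
  expect_gte(class_template("ST_ELEVATION")$st_offset, 0.15)

  # QRS duration at 10% of R amplitude: sinus normal, widening pathological
  expect_lte(qrs_duration(class_template("SINUS_RHYTHM")), 0.100)
  expect_gte(qrs_duration(class_template("SINUS_RHYTHM")), 0.080)
  expect_gte(qrs_duration(class_template("QRS_WIDENING")), 0.120)

  # elevation template exceeds sinus over the ST window
  stw <- st_window(1)
  t <- seq(stw[1], stw[2], by = 1 / 2000)
  elev <- mean(beat_waveform(class_template("ST_ELEVATION"), t))
  sinus <- mean(beat_waveform(class_template("SINUS_RHYTHM"), t))
  depr <- mean(beat_waveform(class_template("ST_DEPRESSION"), t))
  expect_gt(elev, sinus)
  expect_lt(depr, sinus)

  expect_error(class_template("VENTRICULAR_FLUTTER"), "unknown beat class")
})

test_that("beat classes have stable integer codes 0-3", {
  expect_identical(beat_classes(),
                   c("QRS_WIDENING", "SINUS_RHYTHM", "ST_DEPRESSION",
                     "ST_ELEVATION"))
  expect_identical(beat_class_code(beat_classes()), 0:3)
})

test_that("generate_recording places programmed beats exactly", {
  rec <- clean_sinus()
  # 60 bpm, 10 s, no jitter: 10 beats spaced exactly 360 samples
  expect_length(rec$true_r_peaks, 10L)
  expect_true(all(diff(rec$true_r_peaks) == 360L))
  expect_equal(rr_intervals(rec), rep(1.0, 9))
  expect_length(rec$beat_labels, length(rec$true_r_peaks))
  expect_true(all(rec$true_r_peaks <= length(rec$signal$samples)))

  # the peak sample really is the R wave: template maximum at the R time
  expect_gt(rec$signal$samples[rec$true_r_peaks[5]], 0.9)
})

test_that("generate_recording is deterministic and validates arguments", {
  a <- generate_recording("ST_ELEVATION", 8, 360, 80, rr_jitter_frac = 0.05,
                          noise = noise_spec(white_sd = 0.03), seed = 42)
  b <- generate_recording("ST_ELEVATION", 8, 360, 80, rr_jitter_frac = 0.05,
                          noise = noise_spec(white_sd = 0.03), seed = 42)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$true_r_peaks, b$true_r_peaks)

  c <- generate_recording("ST_ELEVATION", 8, 360, 80, rr_jitter_frac = 0.05,
                          noise = noise_spec(white_sd = 0.03), seed = 43)
  expect_false(identical(a$signal$samples, c$signal$samples))

  expect_error(generate_recording("SINUS_RHYTHM", 10, 360, 10), "heart_rate")
  expect_error(generate_recording("SINUS_RHYTHM", 10, 50, 60), "fs")
  expect_error(generate_recording("SINUS_RHYTHM", 1.5, 360, 60), "duration")
})

test_that("generator does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(1)
  set.seed(123)
  invisible(generate_recording("SINUS_RHYTHM", 5, 360, 60, seed = 9))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("add_noise composes additively and reproducibly", {
  rec <- clean_sinus()
  sig <- rec$signal

  expect_identical(add_noise(sig)$samples, sig$samples)  # all zero = identity

  nb <- add_noise(sig, baseline_amp = 0.5, baseline_hz = 0.3)
  d <- nb$samples - sig$samples
  t <- (seq_along(d) - 1) / 360
  expect_equal(d, 0.5 * sin(2 * pi * 0.3 * t), tolerance = 1e-12)
  expect_equal(nb$fs, sig$fs)
  expect_length(nb$samples, length(sig$samples))

  nw <- add_noise(sig, white_sd = 0.05, seed = 4)
  expect_equal(sd(nw$samples - sig$samples), 0.05, tolerance = 0.1)
  expect_identical(add_noise(sig, white_sd = 0.05, seed = 4)$samples,
                   nw$samples)
  expect_error(add_noise(sig, white_sd = -1), "amplitudes")
})

test_that("morphology separation holds on noise-free recordings", {
  st_mean <- function(cls) {
    rec <- generate_recording(cls, 10, 360, 60, rr_jitter_frac = 0, seed = 2)
    stw <- st_window(1)
    i <- rec$true_r_peaks[5] + seq(round(stw[1] * 360), round(stw[2] * 360))
    mean(rec$signal$samples[i])
  }
  expect_lt(st_mean("ST_DEPRESSION"), st_mean("SINUS_RHYTHM"))
  expect_lt(st_mean("SINUS_RHYTHM"), st_mean("ST_ELEVATION"))
})

test_that("recordings round-trip through CSV plus JSON sidecar", {
  rec <- generate_recording("ST_DEPRESSION", 6, 360, 75, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_recording(rec, f)
  back <- read_recording(f)
  expect_identical(back$true_r_peaks, rec$true_r_peaks)
  expect_identical(back$beat_labels, rec$beat_labels)
  expect_identical(back$seed, rec$seed)
  expect_equal(back$signal$samples, rec$signal$samples, tolerance = 1e-7)
})
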