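# ecgflow

Single-lead ECG conditioning, beat segmentation, and image-based
classification in R.

Low-cost single-lead ECG front ends (a heart-rate monitor chip feeding a
10-bit ADC) make continuous rhythm monitoring cheap, but turning their raw
sample stream into a clinically meaningful label requires a full chain:
frequency-domain conditioning, locating each heartbeat, cutting the signal
into single cardiac cycles, and classifying each cycle's morphology.
ecgflow implements that chain as composable, deterministic, individually
tested stages, for signal-processing researchers and engineers who want to
prototype or validate beat-classification pipelines without hardware or
database downloads: a synthetic generator produces recordings of all four
supported morphologies — sinus rhythm, QRS widening, ST depression, ST
elevation — with exact ground-truth R peaks.

## What it computes

* **Conditioning.** DFT band limiting to 0.5–40 Hz and magnitude-threshold
  denoising: after band limiting, spectral bins with magnitude below
  0.2 × the maximum in-band magnitude are zeroed and the signal is
  reconstructed by the inverse transform.
* **Segmentation.** A Pan–Tompkins-style R-peak detector (5–15 Hz
  band-pass → differentiate → square → 150 ms integration → adaptive
  threshold → 200 ms refractory → snap to raw maximum). Each interior beat
  is cut as the half-RR window
  [Rᵢ − RRᵢ₋₁,ᵢ/2, Rᵢ + RRᵢ,ᵢ₊₁/2) around its R peak.
* **Classification.** Beats are rasterised to square grayscale images
  (fixed −1.5..+2.0 mV voltage window, so ST shifts survive) and fed to a
  compact CNN (3 conv blocks + global average pool + 4-way softmax)
  written in-package and gradient-checked; class balancing and the
  per-class half/half train/test split are deterministic under a seed.
* **Evaluation.** From a 4×4 confusion table: accuracy = trace/total,
  per-class recall/precision/F1, macro aggregates, and Cohen's kappa
  κ = (p₀ − pₑ)/(1 − pₑ) with pₑ = Σₖ rowsumₖ·colsumₖ/N².
* **Device agreement.** Paired RR-interval series are compared with a
  Wilcoxon signed-rank test (exact null distribution up to n = 25,
  normal approximation with continuity and tie corrections beyond),
  MA-plot coordinates ((a+b)/2, a−b), and the fraction of pairs inside a
  ±0.1 s band.

## Worked example

```r
library(ecgflow)

# a 30 s ST-elevation recording at 72 bpm with mild sensor noise
rec <- generate_recording("ST_ELEVATION", duration_s = 30, fs = 360,
                          heart_rate_bpm = 72,
                          noise = noise_spec(white_sd = 0.02), seed = 42)
rec
#> <synthetic_recording> ST_ELEVATION: 35 beats, 30.0 s @ 360 Hz (seed 42)

sig   <- bandlimit(rec$signal)            # 0.5-40 Hz conditioning
peaks <- detect_r_peaks(sig)
peaks
#> <rpeak_list> 35 peaks @ 360 Hz
round(head(rr_intervals(peaks), 5), 3)
#> 0.867 0.819 0.842 0.850 0.844

beats <- segment_beats(sig, peaks,
                       labels = rep("ST_ELEVATION", length(peaks$indices)))
beats[[1]]
#> <beat_segment> 303 samples @ 360 Hz, R at 157 (global 463), label ST_ELEVATION
render_beat(beats[[1]], size = 64)
#> <beat_image> 64x64, 126 trace pixels, label ST_ELEVATION
```

All 35 programmed beats are recovered (the detector is exact on clean and
mildly noisy recordings at resting rates), the RR intervals scatter around
the programmed 60/72 ≈ 0.83 s with the configured 3% jitter, and each beat
renders to a deterministic raster ready for the classifier.

Scoring a classifier from its confusion table:

```r
ct <- read_confusion_csv(system.file("extdata", "confusion_resnet.csv",
                                     package = "ecgflow"))
metrics_report(ct)
#> <metrics_report> n = 11796
#>          class recall precision    f1
#>   QRS_WIDENING  0.950     0.958 0.954
#>   SINUS_RHYTHM  0.985     0.968 0.976
#>  ST_DEPRESSION  0.959     0.981 0.970
#>   ST_ELEVATION  0.986     0.974 0.980
#> accuracy  0.97007
#> recall    0.97007 (macro)
#> precision 0.97011 (macro)
#> F1        0.97009 (macro_harmonic)
#> kappa     0.96010
```

The rows are per-class test results over 2949 images each; the aggregate
block shows overall accuracy, macro recall/precision, the macro F1
(harmonic-of-macros convention), and the chance-corrected kappa.

Paired RR agreement between two devices:

```r
w <- wilcoxon_signed_rank(rr_paired(c(1.1, 1.2, 1.3, 1.4, 1.5), rep(1, 5)))
c(V = w$statistic, p = w$p_value)
#>       V       p
#> 15.0000  0.0625
```

Five positive differences put the positive-rank sum at its maximum of 15;
the exact two-sided p is 2/2⁵ = 0.0625.

One call runs the whole chain (simulate → condition → segment → render →
balance/split → train → evaluate) into a timestamped run directory:

```r
run <- run_pipeline(run_config(seed = 1, beats_per_class = 50))
run$report
```

A thin CLI over the same functions lives at `inst/cli/ecgflow.R`
(subcommands `simulate`, `preprocess`, `segment`, `render`, `metrics`,
`validate-rr`, `run`).

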