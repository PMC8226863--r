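---
title: "ecgflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ecgflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ecgflow implements a complete single-lead ECG analysis chain: signal
ingestion, frequency-domain conditioning, R-peak anchored beat
segmentation, beat-to-image rendering, four-class convolutional
classification, and the evaluation layer (confusion-table metrics, Cohen's
kappa, paired RR-interval agreement). This vignette explains the models and
conventions behind each stage, the parameters that matter, and the design
choices that were genuinely open.

## The synthetic beat model

Downstream stages are tested against recordings with known ground truth,
produced by `generate_recording()`. A beat is a sum of five Gaussian bumps
— the P, Q, R, S and T waves — plus a plateau shelf over the ST segment:

$$v(t) = \sum_{w \in \{P,Q,R,S,T\}} a_w
  \exp\!\left(-\frac{(t - c_w)^2}{2\sigma_w^2}\right)
  + \delta_{ST}\,\Pi(t),$$

where $t$ is time relative to the R peak, $a_w$ (mV), $c_w$ (s) and
$\sigma_w$ (s) are per-wave amplitude, centre and width, $\delta_{ST}$ is
the ST offset and $\Pi$ a raised-cosine-edged shelf spanning the gap
between the end of the S wave and the onset of the T wave. The Gaussian
decomposition is the standard analytically controllable synthetic ECG
form: every morphological property used by the tests (QRS duration, ST
level) can be derived from the parameters.

The four class templates (`class_template()`) differ only in clinically
interpretable parameters:

| class | defining parameter | default |
|---|---|---|
| sinus rhythm | none (reference template) | QRS ≈ 90 ms, $\delta_{ST} = 0$ |
| QRS widening | QRS width scale | 1.5 → QRS ≈ 134 ms (≥ 120 ms) |
| ST depression | $\delta_{ST}$ | −0.15 mV |
| ST elevation | $\delta_{ST}$ | +0.20 mV |

QRS duration is measured operationally — the span where the rendered
Q/R/S sum exceeds 10% of the R amplitude — because the morphologies are
defined pictorially in the source material, not numerically. All template
numbers (R = 1.0 mV, P = 0.15 mV, T = 0.3 mV, the ±mV ST offsets) are
package conventions chosen to be physiologically plausible for a chest
lead; they are exposed through `morphology_params()` and not claimed to
reproduce any real database's amplitude statistics.

Beats are placed at programmed R times with mean RR $= 60/\text{HR}$ and
Gaussian RR jitter (sd 3% of RR by default, truncated at ±20%). The P and
T wave centres and the ST shelf stretch linearly with the local RR while
the QRS complex keeps its absolute duration — diastole, not ventricular
depolarisation, absorbs rate variation. The ST measurement window is
[R + 0.06 s, R + 0.20 s] at 60 bpm, scaled linearly with RR; it had to be
fixed explicitly so that ST offsets are testable.

What the generator does *not* emulate: respiratory sinus arrhythmia and
other HRV structure, multi-lead geometry, ectopy, electrode motion
artifacts, or the waveform statistics of any real recording. Noise is
limited to three additive components (sinusoidal baseline wander,
sinusoidal mains interference, white Gaussian noise). A classifier that
separates these synthetic classes perfectly has therefore demonstrated
that the pipeline's plumbing and learning machinery work — not that it
reaches any particular accuracy on clinical data.

## Signal formats and conventions

Sample indices are 1-based with $t = (i-1)/f_s$, the natural R
convention; all documented index examples follow it. Signals carry
voltages in millivolts.

Three formats are supported: a self-describing CSV (`fs=` header, one
sample per line), the WFDB format-212 dialect (text `.hea` header, packed
12-bit `.dat`, MIT `.atr` beat annotations — including SKIP records for
long gaps), and a plain-text ADC serial stream emulating a 10-bit
acquisition front end. The serial scale is affine,
$\text{mV} = (\text{code} - 512) \cdot 1000 \cdot 3.3 / 2^{10}$, a fixed
documented convention (the hardware it emulates specifies only the 3.3 V
reference). Every reader validates its input and every writer round-trips
within the format's quantisation step.

## Frequency-domain conditioning

`bandlimit()` zeroes discrete-spectrum bins outside [0.5, 40] Hz
(conjugate pairs together, so the inverse transform is exactly real) and
`fft_threshold_denoise()` additionally zeroes in-band bins whose magnitude
falls below 0.2 × the maximum in-band magnitude. Conventions fixed here:

* the threshold applies to spectral *magnitude*, not power, and is applied
  *after* band limiting, with the maximum searched in-band;
* the DC bin is always removed (it lies below the 0.5 Hz edge) and is
  excluded from the maximum search;
* an all-zero signal is returned unchanged rather than dividing by a zero
  maximum.

Because bins are only ever zeroed, both operations are energy
non-increasing (Parseval), `bandlimit()` is linear, and the denoiser is
idempotent on signals with well-separated spectral lines — all verified as
property tests.

One measured caveat: on long recordings a periodic ECG concentrates into
many fine harmonics, most of which individually fall below 0.2 of the
dominant line, so the 0.2 threshold also discards QRS energy and degrades
downstream peak detection. The threshold rule is implemented exactly as
specified, but the pipeline's conditioning mode is therefore configurable:
`"bandlimit"` (default), `"denoise"`, or `"none"`.

## R-peak detection and beat segmentation

The detector is a Pan–Tompkins-style energy chain: Butterworth band-pass
to 5–15 Hz (zero-phase), differentiate, square, 150 ms moving-window
integration, adaptive threshold (rolling 2 s mean + 1.5 sd), candidate per
supra-threshold region, 200 ms refractory period, and a final snap to the
raw-signal maximum within ±50 ms. The threshold multiplier k = 1.5 was
fixed during detector development: it recovers every programmed peak with
no false detections on clean synthetic recordings across 60–100 bpm and
keeps sensitivity and positive predictivity at 1.0 under 0.05 mV white
noise at the seeds exercised. A flat signal yields an empty peak list, not
an error. When reference annotations exist (MIT-style `.atr`), they can be
used instead of the detector.

Each interior peak $R_i$ is cut as the half-open window
$[R_i - \lfloor RR_{i-1,i}/2 \rfloor,\; R_i + \lfloor RR_{i,i+1}/2 \rfloor)$
— half the preceding RR interval before the peak and half the following
one after it. Flooring plus half-open bounds guarantees adjacent segments
never overlap; with uniform even RR they tile the interior span exactly.
The first and last beats have no neighbour on one side and are dropped, a
boundary rule the package documents rather than inherits.

## Beat-to-image rendering

`render_beat()` maps a segment onto a `size` × `size` raster (default
256): time resampled linearly to columns, voltage mapped through a *fixed*
global window (−1.5 to +2.0 mV) to rows, 1-pixel connected polyline, trace
black (0) on white (1). The fixed window — rather than per-beat min–max
normalisation — is deliberate: normalising each beat would re-centre the
baseline and erase exactly the ST-level displacement that distinguishes
two of the four classes. Values outside the window clip. PNG is the
default on-disk format because it is lossless and makes pixel-exact
round-trip tests possible; JPEG is available but lossy. At the classifier
boundary images are inverted (trace = 1 on background 0) so that the
sparse trace, not the constant background, drives the activations; this
markedly improves optimisation and is applied consistently in training and
prediction.

## The classifier

The reference architecture, `small_cnn`, is three 3×3 convolution blocks
(8/16/32 filters, ReLU, 2×2 max pooling) followed by global average
pooling and a four-way softmax head. The engine — im2col convolution,
pooling with deterministic argmax routing, Adam/SGD — is written in matrix
algebra inside the package and its backward pass is verified against
central-difference numerical gradients in the test suite. The
`resnet_tl`, `alexnet_tl` and `squeezenet_tl` presets run the same engine
with larger filter banks and report the nominal deep-layer counts of the
published networks they stand in for (177/25/68) for bookkeeping parity;
they always train from random initialisation, since no pre-trained weights
are shipped or downloaded.

Dataset protocol: classes are first balanced by downsampling to the
smallest class without replacement, then split half/half per class with
the training side receiving the ceiling — a class of 5899 yields 2950
training and 2949 test items. Both operations are deterministic under a
seed, and so is training: weight initialisation and batch order derive
from `config$seed`, so identical configurations reproduce identical
confusion tables.

Default training parameters: Adam, learning rate 3e-3, batch 16, ≤ 10
epochs, 64 × 64 input. The input resolution is a package choice (any
multiple of 8 from 32 up is accepted, including the classical 256): at
64 × 64 the four synthetic morphologies remain trivially distinguishable
and the desk-scale experiment — 4 × 200 beats, half/half split, 10 epochs
— is the standard problem size exercised by the test suite and the
acceptance script.

## Evaluation metrics

From a 4×4 confusion table (rows = truth, columns = prediction, fixed
class order): accuracy = trace/total; per-class recall
$= ct_{kk}/\text{rowsum}_k$, precision $= ct_{kk}/\text{colsum}_k$,
F1 $= 2PR/(P+R)$; macro recall/precision are unweighted class means;
kappa $= (p_o - p_e)/(1 - p_e)$ with $p_e = \sum_k
\text{rowsum}_k \text{colsum}_k / N^2$. Two conventions worth making
explicit:

* **Macro F1.** The primary convention is the harmonic mean of macro
  precision and macro recall, which is the convention consistent with the
  published aggregate tables this module reproduces; the arithmetic mean
  of per-class F1 scores (the other common definition) is available via
  `f1_convention = "mean_per_class"`. The two differ in the fourth decimal
  on those tables.
* **Undefined metrics.** A class with a zero row or column sum yields `NA`
  (flagged), never a silent 0; macro aggregates over an `NA` raise an
  undefined-metric error unless `metrics_report(partial = TRUE)` is used
  (the pipeline uses it so a degenerate desk-scale run still produces a
  report).

Metrics are carried at full precision; 3- or 5-decimal rounding is purely
a display concern. With balanced row sums, accuracy equals macro recall
exactly and kappa collapses to $(\text{acc} - 1/4)/(3/4)$ — identities the
tests exploit as cross-checks.

## RR-interval agreement

Two aligned RR series (prototype vs reference monitor) are compared
three ways: a Wilcoxon signed-rank test, MA-plot coordinates
$((a+b)/2,\ a-b)$, and the fraction of pairs within a ±0.1 s band. The
signed-rank test drops zero differences (classic convention; Pratt's
zero-inclusive ranking is available via `zero_method = "pratt"`), assigns
midranks to ties, and is exact for up to 25 non-zero pairs: the null
distribution of the positive-rank sum is built by convolution over doubled
midranks, which is identical to enumerating all $2^n$ sign vectors — and
is proved equal to explicit enumeration for $n \le 10$ in the tests,
including tied cases. Larger samples use the normal approximation with
continuity and tie corrections; the two paths agree to better than 0.01
at the cutoff. Two-sided p-values at α = 0.05 throughout. Alignment of
the two series is the caller's responsibility: the package compares
positionally and provides no beat-matching between devices.

## Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale: 10–30 s
recordings, 4 × 200 beats for the classification experiment, 64 × 64
images, ≤ 10 epochs. These sizes were chosen so the full suite exercises
every stage end-to-end in a couple of minutes on one CPU while leaving
each statistical check comfortable margins. Tie-breaks and degenerate
inputs are all fixed deterministically: max-pool gradient goes to the
first maximal position, prediction takes the first maximal class
probability, flat signals give empty peak lists, all-zero signals pass
through the denoiser unchanged.

## Known limitations

* The detector targets resting sinus-morphology rhythms (60–100 bpm);
  arrhythmia- or tachycardia-specific detection is out of scope.
* The synthetic generator's realism limits are listed above; no claim
  about clinical accuracy follows from synthetic results.
* The mapping from real annotation code sets to the four classes is not
  defined here; real-data experiments must supply their own labels via
  the manifest interface.
* `fft_threshold_denoise()` with the default 0.2 threshold is best suited
  to short windows with a few dominant spectral components; see the
  conditioning section.
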