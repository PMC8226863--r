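Package: ecgflow
Title: Single-Lead ECG Conditioning, Beat Segmentation, and Image-Based Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for single-lead electrocardiogram (ECG)
    analysis: synthetic four-morphology ECG generation (sinus rhythm, QRS
    widening, ST depression, ST elevation) with ground-truth R peaks,
    reading and writing of CSV, WFDB format-212 and ADC serial-stream
    signal formats, FFT band-limiting and magnitude-threshold denoising,
    R-peak detection with half-RR beat segmentation, deterministic
    beat-to-image rendering, a compact convolutional neural network
    classifier over beat images, multiclass confusion-table metrics
    including Cohen's kappa, and paired RR-interval agreement statistics
    (Wilcoxon signed-rank test, MA-plot coordinates, agreement band
    fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
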