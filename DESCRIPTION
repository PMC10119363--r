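Package: lfposc
Title: Oscillation Detection, Phase Synchrony, and Dyskinetic Behaviour
    Analysis for Cortico-Basal-Ganglia LFP Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-structure local field potential
    (LFP) recordings in rodent models of L-DOPA-induced dyskinesia.
    Provides bipolar re-referencing of multi-wire bundles, Welch
    spectrograms, irregular-resampling auto-spectral analysis (IRASA) for
    fractal/oscillatory separation, parametric Gaussian peak detection of
    theta, beta and narrowband-gamma oscillations with goodness-of-fit
    gating, Hilbert-phase synchrony and functional connectivity with
    circular statistics, rotational-behaviour quantification from pose
    keypoints (8-sector full-turn counting, occupancy, speed), abnormal
    involuntary movement (AIM) scoring, and a synthetic-data generator
    with ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
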