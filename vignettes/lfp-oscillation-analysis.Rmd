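---
title: "Detecting dyskinesia-related LFP oscillations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dyskinesia-related LFP oscillations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfposc)
```

## The problem

In the unilaterally dopamine-depleted rat, dopaminergic drugs that relieve
parkinsonian signs also induce abnormal involuntary movements (AIMs,
dyskinesia). Dyskinesia is accompanied by characteristic changes in local
field potentials (LFPs) across the cortico-basal-ganglia network: sharply
tuned narrowband gamma (NBG, 70–110 Hz) oscillations that track the
dyskinetic state, and theta (5–10 Hz) oscillations in deeper nuclei.
Quantifying these phenomena from multi-wire, multi-structure recordings
requires a chain of steps — re-referencing, spectral estimation, separation
of rhythmic from arrhythmic (fractal) power, parametric peak detection,
phase-synchrony analysis — plus parallel quantification of the behaviour
itself (AIM rating composites, full-body rotations, locomotion).

`lfposc` implements this chain as composable functions, together with a
synthetic-data generator that produces sessions with known ground truth so
every stage can be validated end to end.

## Preprocessing

Wideband signals are reduced to the LFP band by a zero-phase
(forward–backward) 8th-order Butterworth low-pass at 500 Hz followed by
downsampling to 2000 Hz (`decimate_lfp`). We filter forward–backward,
doubling the effective order, because the phase-synchrony stage downstream
must not inherit filter phase distortion; a causal filter would delay each
frequency differently and bias phase differences between structures that
were filtered identically only in magnitude.

Within every structure, all unique pairs of wires are subtracted
(`make_bipolar_pairs`, lower wire id minus higher, for determinism — power
and coherence magnitudes are sign-invariant). Bipolar derivation removes
signals common to both wires (volume-conducted activity, shared artifacts)
and emphasises local sources; with `k` usable wires a structure contributes
`k(k-1)/2` derivations.

Channel exclusion is automated rather than visual: wires with a standard
deviation below 0.1 µV are flagged as flat lines, and wires whose broadband
RMS exceeds 5× the median RMS of their structure are flagged as noise
outliers (`exclude_noisy_channels`). Both thresholds are configurable; the
defaults were chosen so that clean synthetic sessions produce zero
exclusions while dead and saturated channels are always caught.

## Spectral analysis and fractal separation

`welch_spectrogram` estimates a time series of power spectral densities
over 0–250 Hz using an 8-s Hann window advanced in 4-s steps (50% overlap),
so the spectrogram — and the oscillation detector — has one column every
4 s and a native frequency resolution of 0.125 Hz.

LFP spectra mix rhythmic peaks with an arrhythmic power-law ("fractal")
background. `irasa_fractal` separates the two by irregular-resampling
auto-spectral analysis: the windowed segment is resampled by each factor
`h` in a set (default 1.1, 1.15, …, 1.9) and by `1/h`; a power-law spectrum
is invariant under the geometric mean of each (h, 1/h) PSD pair, while
rhythmic peaks are displaced to `f·h` and `f/h` and suppressed by the
median across factors. The normalized spectrum

$$S_{dB(fractal)}(f) = 10\,\log_{10}\frac{S(f)}{S_{fractal}(f)}$$

is zero (in expectation) wherever the signal is purely fractal and positive
at genuine oscillations, which makes peak heights comparable across
structures and background slopes. Mains contamination at 50 ± 2 Hz and its
harmonics (100 ± 1, 150 ± 1, 200 ± 1 Hz) is excised by masking those
frequency bins (`excise_line_noise`); masked bins are flagged, never
zeroed, and are excluded from peak fitting and averaging rather than
interpolated — interpolation would fabricate data under the fit.
Per-pair normalized spectrograms are averaged into one representative
spectrogram per structure (`average_structure`), with masked bins skipped
bin-wise.

Three numerical choices deserve explanation:

* **Resampling method.** Resampling inside IRASA uses the Fourier method
  (spectrum truncation/zero-padding), which is exact for band-limited
  content and applies an ideal anti-aliasing filter implicitly. Resampled
  lengths are snapped to 5-smooth integers so the FFTs stay fast; the
  effective resampling factors differ from the nominal set by well under
  1%, which is immaterial because the factor set itself is a heuristic
  sweep.
* **Sub-window averaging.** All PSDs entering the IRASA ratio — the mixed
  spectrum and every resampled spectrum — are estimated with 7
  half-overlapped Hann sub-windows inside each 8-s window (configurable via
  `n_sub`). A single-taper periodogram carries multiplicative
  chi-squared(2) noise whose logarithm is biased by −2.5 dB, and the
  geometric-mean/median combination in the fractal estimator has a
  different bias, so single-taper ratios do not average to 0 dB even on
  purely fractal input. With consistent sub-averaging the normalization is
  neutral to within a few tenths of a dB and the per-bin noise is small
  enough for goodness-of-fit gating to be meaningful. `n_sub = 1` restores
  the literal single-taper estimate if desired. The sub-averaged frequency
  resolution (0.5 Hz at the defaults) is ample for peaks whose widths are
  ≥ 1 Hz.
* **Windowing of IRASA.** IRASA is applied per 8-s analysis window so that
  the fractal estimate, the detection grid, and the spectrogram share one
  time base. Applying it to whole recordings instead would average over
  state changes (drug onset/offset) that this analysis is designed to
  resolve.

## Oscillation detection

For each 4-s column and each band, the spectral segment of interest
([1, 15] Hz for theta, [8, 48] Hz for beta, [40, 120] Hz for NBG) is fitted
with a five-parameter model

$$y(f) = A e^{-\left(\frac{f-B}{C}\right)^2} + Df + E,$$

a Gaussian peak (height `A` in dB_fractal, frequency `B` in Hz, width `C`
in Hz) on a linear background (slope `D`, offset `E`), by
Levenberg–Marquardt least squares (`fit_peak_model`). Because the
single-peak model has local minima when spectra are multi-modal, `B` is
multi-started across the band range (5 starts) and the fit with the
smallest residual sum of squares is kept; the background is initialized
from an ordinary line fit and `A` from the maximum residual above it.

A positive detection is declared when all parameters and the goodness of
fit fall inside limit values (`classify_detection`): by default `A` ≥ 1.5
dB_fractal, `B` inside the band's detection range (5–10, 12–35, or 70–110
Hz), `C` in [0.5, 15] Hz ([0.3, 4] Hz for theta, whose peaks are narrow),
|`D`| ≤ 0.2 dB/Hz, and R² ≥ 0.7. These limits are calibrated on the
synthetic generator so that pure-fractal control structures yield at most
5% false positives while physiologically sized peaks are detected
reliably; all of them are configurable. The detection rate over an
analysis window is the mean of the binary outcome, and summaries of peak
height and frequency are reported only when the rate exceeds 5% —
below that, the handful of positive fits is too small to characterise an
oscillation. Beta-band fitting is implemented and tested but excluded from
default reports: beta desynchronisation under dopaminergic treatment is
well documented elsewhere and is not the target of this analysis.

Treatment-specific peak-dyskinesia windows are encoded as presets
(`peak_window`): 20–60 min post injection for the D1 agonist SKF82958,
40–80 min for L-DOPA, sumanirole, and vehicle. The association between
oscillation power and dyskinesia is quantified by Spearman rank correlation
of per-period peak heights against global AIM scores
(`correlate_power_aims`).

Detection operates on the structure-averaged spectrogram rather than on
per-pair spectra: averaging first suppresses the estimator noise that
individual bipolar derivations carry, and one binary outcome per structure
per bin is what the detection-rate summaries require.

## Phase synchrony and functional connectivity

For recordings where NBG oscillations were detected, signals are band-pass
filtered ± 5 Hz around the median of the fitted peak frequencies, pooled
across the structures involved over the analysis window
(`nbg_median_frequency`, `bandpass_about_median`; 4th-order Butterworth,
forward–backward). A single common passband keeps phase differences
comparable across pairs — a per-pair passband would make each pair's phase
refer to a slightly different oscillation. The instantaneous phase is the
argument of the analytic signal (`instantaneous_phase`); the first and
last 0.5 s are discarded as edge transients.

For every cross-structure wire pair, the circular mean `Δφ` and the mean
resultant vector length `r` of the phase-difference series are computed
(`pair_phase_stats`). Structure-level functional connectivity is the mean
`r` over all wire pairs; the structure-level phase difference averages `Δφ`
only over pairs with `r` > 0.5, because a weak resultant means the phase
estimate is dominated by noise (`structure_coupling`). When no pair passes
the filter, the phase difference is reported missing rather than guessed.
Phases are computed on per-wire (monopolar) signals by default — pair
phases between single wires in two structures — with a bipolar mode
available; the monopolar default matches the wire-pair formulation of the
statistics. Analysis is restricted to 4-s bins in which both structures
have a positive NBG detection (configurable), since the phase of an absent
oscillation is noise.

The one-sample mean-angle test (`mean_angle_test`) tests whether a
structure pair's mean phase difference differs from 0° via the circular
confidence interval for the mean direction; with `n` structure pairs
tested, a Bonferroni-corrected `alpha/n` is supported. Phase differences
convert to conduction delays as `delay = (Δφ/360)/f` (`phase_to_delay`),
with the convention that a positive value means the first structure leads.

## Behaviour

`derive_pose` reduces a 7-keypoint pose table (nose, both ears, head top,
body center, tail base, tail tip) to centroid, front (mean of the four
head points), and heading (direction from tail base towards the front),
keeping only frames where every keypoint's detection likelihood exceeds
0.9.

Full 360° turns are counted on the heading binned into 8 absolute 45°
sectors (`count_full_turns`): an online counter accumulates same-direction
sector transitions and declares a turn at 8; a reversal discards the
incomplete rotation, with the last angle of the discarded rotation
starting the next count. Two conventions needed fixing where the verbal
rule is ambiguous. First, sector boundaries are absolute
([0°, 45°), [45°, 90°), …), not relative to where a turn started; on the
sector-quantized heading this makes the online counter provably equivalent
to a batch oracle that scans maximal monotone runs and credits one turn
per 360° of accumulated rotation, and the test suite enforces exact
agreement on randomized series including reversals and multi-sector
jumps. Second, frames dropped by the likelihood filter leave gaps: a gap
longer than 1 s resets the running count (the animal may have turned
arbitrarily while unobserved), while shorter gaps are bridged. Both the
gap threshold and the mapping of counter-clockwise image rotation to
"contralateral" (appropriate for a right-hemisphere lesion viewed from
above; configurable) are explicit parameters.

Per-turn distance and duration come from the centroid path between a
turn's start and end frames (`turn_metrics`). Overall motor activity is
the fraction of 1 × 1 cm squares of the arena visited by the centroid per
1-min bin (`occupancy_fraction`); the denominator counts squares whose
center lies inside the 55-cm arena circle — using the bounding square
would deflate the fraction with area the animal can never visit. Speed is
the centroid displacement across a sliding 1-s window (`compute_speed`).

AIM score sheets hold a severity and an amplitude score (0–4 integers) per
subtype (axial, limb, orolingual) per monitoring period — 1 min every
5 min for the first 20 min post injection, then every 10 min. The
composite per subtype is severity × amplitude (0–16), the global score per
period sums the three composites (0–48), and session-total and peak-window
scores sum globals (`score_aims`).

## The synthetic-data generator

The generator (`generate_session`, `generate_trajectory`,
`generate_aim_series`) emulates the statistical structure the analysis
assumes, not the biophysics that produces it:

* **Fractal background** — spectral shaping of white noise with an
  amplitude profile `f^(-χ/2)` (`generate_fractal_series`), giving exact
  control of the power-law exponent; variance (µV²) is set analytically,
  so `fractal_psd_level` / `fractal_scale_for_psd` can place backgrounds
  of different exponents at a common level.
* **Oscillations** — a sinusoid whose instantaneous frequency follows an
  Ornstein–Uhlenbeck process (correlation time 0.15 s) with stationary SD
  equal to the requested spectral width, so the ensemble PSD peak is
  approximately Gaussian, matching the detector's model
  (`generate_oscillation`). Presence over time is gated by an envelope in
  [0, 1]; `trapezoid_envelope` mimics drug-response time courses
  (onset, sustained plateau, offset).
* **Sessions** — every wire receives an independent fractal realization of
  its structure's spectrum, the shared oscillatory sources of its
  structure (delayed by the structure's phase lag), a bundle-wide
  common-mode artifact identical on all wires (it must cancel exactly in
  bipolar derivations, and does), 50 Hz line noise, and white sensor
  noise. Oscillatory sources are picked up with per-wire gains spread
  around 1 (SD 0.5 by default, drawn as stratified normal quantiles per
  bundle): wires a few hundred microns apart see a local source at very
  different strengths, and it is exactly this heterogeneity that lets
  local oscillations survive bipolar subtraction. A source shared by
  perfectly identical pickup would — correctly — vanish from every bipolar
  pair, and a generator built that way could never exercise the detector.
  The default rate is 2000 Hz (the LFP rate) for desk-scale runtimes; the
  30 kHz wideband path is exercised through `decimate_lfp` directly.
* **Trajectories** — a rigid 7-keypoint body template is rotated along the
  heading (integrated from a supplied angular-velocity function) and
  translated along a circular locomotor path inside the 55-cm arena at
  25 frames/s, with Gaussian keypoint jitter and likelihood dropouts.
  Ground-truth turn counts credit one turn per full 360° of same-sign
  rotation.
* **Seeding** — a single master seed spawns fixed per-component substreams,
  so sessions are bit-reproducible while components stay independent.

Ground truth is aligned to the 4-s detection grid: a bin is labelled
"oscillation present" when the mean envelope over its 8-s window exceeds
0.5, and true pairwise phase differences follow from the per-structure
lags (`lag_b − lag_a`).

What the generator does **not** emulate: spikes and unit activity,
anaesthesia transients, electrode drift, movement artifacts with
broadband signatures, non-stationary fractal exponents, or video frames
(keypoints are the input, as pose estimation is upstream of this
package). Passing the validation suite therefore demonstrates that the
pipeline recovers what it claims from signals with the assumed structure —
power-law background plus Gaussian-peaked narrowband rhythms — not that it
is robust to every artifact class in real recordings.

## Validation problem sizes

The package's validation suite exercises the full pipeline at sizes chosen
to keep a complete run in the minutes range: fractal-neutrality and
peak-preservation ensembles use 136-s series (33 analysis windows) per
background exponent; end-to-end detection-rate recovery uses a 264-s
two-structure session (4 wires per structure, 64 analysis bins, true
presence fraction exactly 0.5 by construction of the envelope); phase-lag
recovery uses 72-s two-structure sessions at lags of 0°, 15°, 30°, 45°;
the null (independent sources) and turn-counting oracle checks use 100 and
200 randomized replicates respectively. `scripts/acceptance.R` re-runs the
same scenarios from a command-line seed and writes the recovered
quantities as JSON.

## Known limitations

* The peak model admits one peak per band; genuinely bimodal spectra
  within a fit window converge to the stronger mode and are only flagged
  through depressed R².
* Detection-limit defaults are calibrated against this generator's noise
  statistics; recordings with different estimator noise (other window
  lengths, pair counts) may need recalibrated limits, which is why all
  limits are parameters.
* The sector-based turn counter can disagree with continuous rotation by
  up to one sector (45°) at run boundaries; at 25 frames/s this is far
  below a full turn but is the reason equivalence is stated on the
  sector-quantized heading.
* IRASA's fractal estimate is only defined up to `nyquist / max(hset)`
  (526 Hz at the defaults — far above the 250 Hz analysis range, so no
  practical restriction here).
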