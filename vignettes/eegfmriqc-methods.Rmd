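---
title: "Quantifying residual signal quality in simultaneous EEG-fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying residual signal quality in simultaneous EEG-fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegfmriqc)
```

## The problem

Recording EEG inside an MR scanner buys temporal resolution at the price
of artifact: the switching imaging gradients induce a TR-periodic
contamination orders of magnitude above the EEG, and cardiac pulsation in
the static field adds a ballistocardiogram (BCG) locked to each QRS
complex. Conversely, the EEG hardware perturbs the MR signal. Even after
state-of-the-art correction, *residual* effects remain, and they are
often regional and frequency-specific rather than global. This package
implements a quantitative workflow for deciding whether simultaneous
acquisition is acceptable for a given study: clean the EEG, quantify its
spectrum per electrode, summarize spatial inhomogeneity with a single
statistic, map the temporal signal-to-noise ratio (TSNR) of the fMRI
series, and test condition differences with design-matched statistics.

Four recording conditions structure every comparison: EEG recorded fully
separately from fMRI; EEG recorded in the scanner control room; EEG
recorded inside the bore before image acquisition; and EEG recorded
during image acquisition. Signal interference is expected to grow along
that ordering.

## EEG cleaning chain

The pipeline order is fixed: gradient-artifact correction on the raw
recording, resampling to 500 Hz, zero-phase 0.5-30 Hz Butterworth
band-pass (design order 2), QRS detection, pulse-artifact subtraction,
optional bad-channel interpolation, average re-referencing, and epoching
with baseline correction. Conditions without gradient or pulse artifact
skip those stages.

**Average artifact subtraction (AAS).** The gradient artifact repeats
every TR; with scanner/amplifier clock synchronization the repetition is
exact in samples (the code refuses recordings whose TR interval varies by
more than one sample). For each channel and TR epoch the mean of the 25
nearest epochs — 12 before, the epoch itself, 12 after, truncated at the
recording edges — is subtracted. Centring the window is our choice; the
classic description leaves it open. No sub-sample realignment is applied,
which is exactly right under clock synchronization and wrong without it.

**QRS detection.** The supervised steps of a typical semi-automatic
workflow are automated: (1) FastICA (tanh contrast, symmetric
decorrelation, written for this package) decomposes the cleaned EEG; a
small component count (default 6) is used because the BCG topography is
low-rank and a small basis stabilizes the decomposition; (2) each
component is scored by the maximum of its normalized autocorrelation over
physiological RR lags (60/110 s to 1.5 s); (3) the best component is
searched for peaks: local maxima, thinned so that no two peaks are closer
than 60/110 s (heart rate assumed below 110 bpm; larger peaks win), then
thresholded on peak prominence. The threshold a human would read off a
prominence histogram is replaced by the valley of a two-class Otsu split
of the log-prominences; the split is only accepted when the two classes
differ by at least a factor of 4 in prominence, so a homogeneous set of
genuine beats is never cut in half. A `prominence` argument preserves the
supervised path. (4) The initial peaks seed a second pass: the dominant
peak-locked topography (first singular vector of the peak-triggered
average) defines a matched spatial filter, and detection is repeated on
the filtered signal. This replaces manual mark correction and, on
synthetic sessions, brings ICA-route detection into full agreement with
detection on a simultaneously recorded ECG. When an ECG trace is
available it is used directly.

**Pulse subtraction.** Around each R peak an epoch spanning
`[-0.25, +0.75]` of the median RR interval is cut, and the subtracted
template is the Gaussian-weighted mean of the 20 nearest epochs, weights
`exp(-(i-j)^2 / (2 * 5^2))` in epoch index. Templates are estimated from
the uncorrected data; overlapping windows (RR jitter) are resolved in
peak order, each window clipped to start after the previous one so no
sample is corrected twice. The template is subtracted as estimated —
without per-epoch amplitude refitting — which is the plainest reading of
the weighted-mean-template method; the per-epoch amplitude jitter that
survives is visible in the ground-truth recovery numbers below.

**Filters.** Resampling low-passes at 0.9 of the target Nyquist with a
zero-phase FIR whose length scales with the decimation ratio, then
evaluates the new grid; event latencies are rescaled and rounded. The
band-pass is applied forward-backward (`filtfilt`) with odd-reflection
padding: zero phase, squared magnitude (effective order 4). Whether the
original tooling filtered once or twice is not knowable from its
description; zero-phase is chosen because latency distortion would bias
QRS-locked windows. Channel means are removed before filtering so DC maps
to exactly zero.

**Interpolation and reference.** Bad channels are replaced by
inverse-distance-weighted (power 2) means over great-circle distances on
the unit sphere — simpler than spherical splines and exact at electrode
positions. The average reference subtracts the mean over a channel subset
at every sample; using the full montage versus a common subset changes
every channel by the same per-sample constant, which cancels in all
within-montage contrasts. Epoch windows are half-open `[start, end)` in
seconds with 0-based sample latencies, so a 2.6 s window at 500 Hz is
exactly 1,300 samples.

## Spectral quality metrics

`fft_sq_amplitude()` computes single-sided squared FFT amplitudes
`A^2(f)` on a 0-65 Hz grid, normalized by window coherent gain so that a
sinusoid of amplitude *a* contributes exactly `a^2` at its bin. Continuous
data use Hann-tapered 2 s segments with 50% overlap (0.5 Hz resolution);
epoched data are transformed per epoch and averaged. The rectangular
window makes the single-sided Parseval identity `sum A^2 = 2 var(x)`
exact and is used for calibration checks; the Hann default trades about a
factor 1.5 of broadband-power calibration (its equivalent noise
bandwidth) for leakage control. All condition comparisons are invariant
to this common scale.

Band summaries average `A^2(f)` over 2 Hz spans around every integer
centre frequency 1-64 Hz, using the half-open convention `[c-1, c+1)` so
each bin belongs to exactly two bands and none is counted twice within a
band. The **index of dispersion** — sample variance (n-1 denominator)
over electrodes divided by the mean over electrodes — is the headline
inhomogeneity statistic: zero for a spatially flat topography and
covariant under common rescaling (scaling all electrodes by *k* scales it
by *k*), so it responds to *relative* spatial structure at any overall
power level. The 15-25 Hz average is the band of interest because the
scanner-induced channel-gain inhomogeneity concentrates there.

## Statistics

All designs follow the study's own conventions: subjects enter two-way
ANOVAs as replicates (not as a factor), giving error degrees of freedom
`ab(r-1)` — (1, 59, 59, 480) for 2 conditions x 60 electrodes x 5
subjects, (1, 25, 25, 208) for the 26 left-right pair differences, and
(1, 1, 1, 16) for the per-pair 2 x 2 ANOVAs. The sums of squares are the
closed-form balanced decomposition, cross-checked in the tests against
the projection-based linear-model fit; unbalanced input is an error, not
a silent fallback. FDR control is Benjamini-Hochberg (the plain "FDR"
reading). The percentile bootstrap resamples subjects with replacement
and reports the percentile of zero among resampled mean differences, with
a mid-rank tie convention so identical conditions give exactly 50%.
"Instantaneous movement" is the Euclidean norm of the volume-to-volume
translation difference in mm; rotations are excluded because the mm unit
implies translations (converting rotations would require an arbitrary
head radius).

## fMRI quality

TSNR is the voxelwise temporal mean over the sample (n-1) standard
deviation; zero-variance voxels are flagged invalid and excluded
everywhere. Tissue-compartment summaries (mean, median, GM/WM ratio) feed
the bootstrap for global effects. Group contrasts are voxelwise paired
t-tests on condition differences with cluster formation at one-sided
voxel p < 0.001 per directed contrast and 18-connectivity (faces and
edges, not corners). Cluster-level family-wise error control uses
sign-flip permutation: with n subjects, all `2^n` flips of the subject
differences are enumerated (n = 5 gives 32, so the smallest attainable
cluster FWE p is 1/32 = 0.03125), and a cluster's p is the proportion of
flips whose maximum suprathreshold cluster — in the same contrast
direction — reaches its size. This replaces random-field-theory cluster
inference deliberately: it is assumption-free, exactly enumerable at
small n, deterministic, and targets the same error rate; cluster sizes
and peaks remain comparable to parametric results only qualitatively.
Spatial preprocessing (realignment, normalization) is an input contract:
the package consumes aligned series, phantoms, or sidecar motion
parameters, and provides the 8 mm FWHM separable Gaussian smoother
(truncated-kernel renormalization at edges) applied to TSNR maps before
group testing.

## Synthetic sessions and what they show

The generator is the test bed: 1/f background (spectral shaping of white
noise, exponent 1, 10 uV RMS), alpha (10 +/- 1 Hz, 4 uV) and beta (20 +/-
2 Hz, 2 uV) band noise, 50 Hz line interference (2 uV), and a 15-25 Hz
band-limited component whose per-channel gain carries the condition
structure: opposite left-right sign on the two amplifiers (amplifier 1
left below right, amplifier 2 the reverse), with asymmetry and scale
growing across presets `separate` (0.05, x1), `outside` (0.1, x1.2),
`pre_acquisition` (0.45, x2) and `simultaneous` (1.0, x5). The gradient
artifact is a sum of slice-frequency harmonics (36 slices / 2.0 s TR = 18
Hz) with 1/k amplitude decay, 1000 uV RMS — two orders above the EEG —
drifting 1% per minute; the published setups do not quantify their
gradient amplitude, so this is an order-of-magnitude choice, not a
hardware calibration. The pulse artifact is a three-Gaussian waveform (R
spike, early undershoot, T-like bump) scaled 30 uV by a smooth scalp
gain, inserted at R peaks with RR ~ Normal(60/HR, sd) truncated at 60/110
s (defaults 65 +/- 3 bpm) and 5% epoch-to-epoch amplitude jitter; a sharp
synthetic ECG trace is generated alongside and flagged non-EEG. The fMRI
phantom is a concentric-ellipsoid head (CSF core, WM, GM shell) with
tissue-specific baselines and noise SDs, linear drift, and an optional
posterior noise increase in one condition, so the true TSNR field is
known exactly. Identical parameters and seed give bit-identical sessions.

Default sizes in the tests and the acceptance script — a 24-channel
montage subset, 500 Hz, 60-120 s sessions, five subjects, and 12 x 12 x 6
phantoms with 60 volumes — are chosen so ground-truth recovery is
comfortably powered while the whole suite runs in a few minutes; the
statistics scale to full 60-channel, 5 kHz sessions unchanged.

What passing these tests shows: the correctors remove what they model
(periodic artifact to numerical zero; >= 40 dB at slice harmonics; >= 80%
QRS-locked variance), detection is essentially perfect when a cardiac
signal exists, the statistics have their nominal error rates, and the
injected condition structure (amplifier-patterned asymmetry, dispersion
ordering, posterior TSNR deficit) is recovered. What they do not show:
robustness to head motion (the generator assumes still subjects, as the
AAS precondition requires), non-stationary artifact morphology,
electrode-position error (the packaged montage is an idealized symmetric
layout), susceptibility or spatial-preprocessing effects, or any
biophysical realism of the background EEG.

## Known limitations

* **Distortion floor of template averaging.** Any corrector that
  subtracts an average of neighbouring artifact epochs re-injects those
  epochs' neural signal. With neural content independent across epochs,
  25-epoch AAS contributes RMS `sigma/5` and the 20-neighbour Gaussian
  pulse template a further `sqrt(sum w~^2) ~ 0.33 sigma` inside the QRS
  windows that tile the recording, a combined floor near `0.39 sigma`. The
  end-to-end checks measure ~33% RMS distortion of the neural signal on
  the default simultaneous session — honest, and inherent to the method
  class, not a tuning artifact. Artifact-specific power is nonetheless
  suppressed below 1% of its uncorrected level, and condition contrasts
  of band power are unaffected to first order because the re-injected
  noise is spatially and spectrally unstructured.
* **Bootstrap coverage at n = 5.** The subject-level percentile bootstrap
  is honest but coarse: under a true null, the percentile of zero falls
  inside (2.5, 97.5) only ~83.5% of the time (all-same-sign samples alone
  account for 6.25%). Percentiles near the tails at this sample size are
  screening evidence, not calibrated tests.
* **ICA identifiability.** With dense independent per-channel noise the
  BCG component is not cleanly separable; the matched-filter second pass
  compensates, but a recorded ECG channel remains the preferred
  detection signal.
* The per-epoch FFT default treats task data epoch-wise; a
  `segment_s`/continuous mode covers continuous rest fragments. Whether
  one or the other is used only changes leakage, not condition ordering.
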