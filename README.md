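# eegfmriqc

Quantitative quality control for simultaneous EEG-fMRI recordings.

Simultaneous EEG-fMRI trades artifact for temporal resolution: imaging
gradients contaminate the EEG with a TR-periodic artifact orders of
magnitude above the signal, cardiac pulsation in the static field adds a
QRS-locked ballistocardiogram, and the EEG hardware in turn perturbs the
MR signal. Even after state-of-the-art correction, residual effects
remain — often regional and frequency-specific. This package is for
EEG-fMRI methodologists and lab engineers who need to decide, for their
own setup, whether those residuals are acceptable in the regions and
frequency bands their experiments care about.

It implements:

* the MR-environment EEG cleaning chain: sliding **average artifact
  subtraction** (mean of the 25 nearest TR epochs per channel),
  ICA-assisted **QRS detection** (autocorrelation component scoring,
  minimal peak distance 60/110 s, automated prominence threshold, and a
  matched-spatial-filter refinement pass), **Gaussian-weighted
  mean-template pulse subtraction** (template for epoch *i* is
  `sum_j w_ij x_j / sum_j w_ij`, `w_ij = exp(-(i-j)^2/50)` over the 20
  nearest epochs), polyphase resampling, zero-phase 0.5-30 Hz Butterworth
  filtering, spherical bad-channel interpolation, average re-referencing,
  and epoching;
* spectral quality metrics: single-sided squared FFT amplitudes `A^2(f)`
  on a 0-65 Hz grid, 2 Hz band means around integer centre frequencies,
  and the **index of dispersion** `Var_e[A^2] / Mean_e[A^2]` across
  electrodes — the headline spatial-inhomogeneity statistic;
* fMRI quality: voxelwise **TSNR** `mu(X)/sigma(X)`, tissue-compartment
  metrics, 8 mm Gaussian smoothing, and paired group contrasts with
  **sign-flip permutation cluster inference** (voxel p < 0.001,
  18-connectivity, all `2^n` flips enumerated — minimum cluster FWE p of
  1/32 at n = 5);
* the condition-comparison statistics: paired t per centre frequency
  with Benjamini-Hochberg FDR, balanced two-way ANOVAs (closed-form sums
  of squares; df structures (1, 59, 59, 480), (1, 25, 25, 208),
  (1, 1, 1, 16) for the standard designs), electrode-pair analyses,
  subject-level percentile bootstrap, and head-movement summaries;
* topographic comparison reports (azimuthal-equidistant projection,
  inverse-distance interpolation, PNG + HTML + machine-readable TSV);
* a synthetic EEG-fMRI session generator with full ground truth
  (injected artifact templates, true R-peak times, channel gains, true
  TSNR fields) emulating the four recording conditions `separate`,
  `outside`, `pre_acquisition`, `simultaneous`.

## Worked example

Simulate a simultaneous session on the packaged 60-channel montage,
clean it, and quantify the 15-25 Hz band:

```r
library(eegfmriqc)

mont <- standard_montage()
p <- preset_eeg_params("simultaneous", montage = mont,
                       fs = 1000, duration = 60, seed = 1)
sess <- generate_eeg_session(p)
sess$recording
#> <eeg_recording> 60 ch x 60000 samples @ 1000 Hz (60.0 s), 48 events,
#>                 ref=FCz, condition=simultaneous

res <- clean_eeg(sess$recording, ecg = sess$ecg, target_fs = 500)
res$qrs
#> <qrs_detection> 65 peaks (source=ecg, min distance 0.545 s)

sp   <- band_means(fft_sq_amplitude(res$recording, fmax = 65))
band <- band_mean_range(sp, 15, 25)
round(band[c("F3", "F4", "FC3", "FC4", "C3", "C4")], 2)
#>    F3    F4   FC3   FC4    C3    C4
#>  0.93 32.64 31.79  0.99  1.07 32.70
index_of_dispersion(band)
#> [1] 14.09726
```

The band values show the injected amplifier-patterned inhomogeneity:
on amplifier-1 pairs (F3/F4, C3/C4) the left electrode is low and the
right high, on amplifier-2 pairs (FC3/FC4) the reverse — an alternating
left-right pattern that a flat scalp should not produce. The index of
dispersion condenses it into one number per band: a spatially
homogeneous topography gives 0, and here the 15-25 Hz value of 14.1 uV^2
flags strong inhomogeneity. Compare conditions with
`dispersion_curve()`, `paired_t_per_frequency()`, `anova2_balanced()`
and `comparison_report()`; map fMRI quality with `tsnr_map()`,
`compartment_metrics()` and `paired_group_contrast()`.

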