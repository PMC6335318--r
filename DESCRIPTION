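Package: eegfmriqc
Title: Residual Signal-Quality Assessment for Simultaneous EEG-fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative quality control for simultaneous EEG-fMRI
    recordings. Implements the MR-environment EEG preprocessing chain
    (sliding average-artifact subtraction of the gradient artifact,
    ICA-assisted QRS detection, Gaussian-weighted mean-template pulse
    artifact subtraction, resampling, zero-phase Butterworth filtering,
    spherical bad-channel interpolation, average re-referencing and
    epoching), FFT squared-amplitude band metrics with the across-electrode
    index-of-dispersion statistic, temporal signal-to-noise ratio (TSNR)
    mapping for fMRI with tissue-compartment metrics and sign-flip
    permutation cluster inference, the associated condition-comparison
    statistics (paired t per frequency with FDR, balanced two-way ANOVAs,
    electrode-pair analyses, percentile bootstrap, motion summaries), and
    topographic comparison reports. A synthetic EEG-fMRI session generator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    pracma,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
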