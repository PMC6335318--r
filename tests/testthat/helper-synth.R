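# Shared fixtures, all generated in code.

# A small but structurally complete montage: pairs on both amplifiers
# plus midline electrodes.
tiny_montage <- function() {
  labels <- c("C1", "C2", "C3", "C4", "Cz", "F1", "F2", "F3", "F4",
              "Fz", "P3", "P4", "Pz")
  amp <- c(2, 2, 1, 1, 1, 2, 2, 1, 1, 1, 1, 1, 1)
  montage(labels, eegfmriqc:::ideal_1005_position(labels), amp)
}

# Mid-sized montage for recovery tests: 10 pairs (5 per amplifier) + 4
# midline, subset of the packaged layout.
mid_montage <- function() {
  montage_subset(standard_montage(),
                 c("F3", "F4", "C3", "C4", "P3", "P4", "FC5", "FC6",
                   "CP5", "CP6",
                   "F5", "F6", "C1", "C2", "P5", "P6", "AF3", "AF4",
                   "PO7", "PO8",
                   "Fz", "Cz", "Pz", "Oz"))
}

# Recording with a strictly TR-periodic artifact and optional neural
# signal, for average-artifact-subtraction oracles.
periodic_artifact_recording <- function(n_epochs = 30, L = 100, fs = 500,
                                        n_ch = 3, template = NULL,
                                        neural = NULL, lead_in = 50) {
  if (is.null(template))
    template <- matrix(sin(2 * pi * seq_len(L) / 20), n_ch, L, byrow = TRUE) *
      (1:n_ch)
  n <- lead_in + n_epochs * L + lead_in
  data <- matrix(0, n_ch, n)
  if (!is.null(neural)) data <- neural
  onsets <- lead_in + (seq_len(n_epochs) - 1L) * L  # 0-based
  for (e in seq_len(n_epochs))
    data[, onsets[e] + seq_len(L)] <- data[, onsets[e] + seq_len(L)] + template
  eeg_recording(data, fs,
                events = data.frame(latency = onsets, label = "tr_onset"),
                condition = "simultaneous")
}

# Small cleaned session for spectral/statistical fixtures: per-subject
# 15-25 Hz band values with an amplifier-patterned asymmetry.
synth_band_values <- function(mont, asym, scale, n_sub = 5, noise = 0.05,
                              seed = 1) {
  set.seed(seed)
  g <- amplifier_band_gain(mont, asym = asym, scale = scale)
  t(sapply(seq_len(n_sub), function(s)
    g^2 * (1 + noise * stats::rnorm(length(g)))))
}
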