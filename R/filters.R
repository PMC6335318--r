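#' Resample a recording
#'
#' Anti-aliased resampling: when changing rate, the signal is low-pass
#' filtered at 0.9 times the target Nyquist frequency with a zero-phase
#' FIR filter and evaluated on the new sample grid. Event latencies are
#' rescaled and rounded to the nearest sample. The rate ratio must be
#' rational with a reasonable denominator (integer decimation such as
#' 5000 -> 500 Hz is the common case).
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate, Hz (at most `rec$fs`).
#' @return The resampled `eeg_recording`.
#' @export
resample_eeg <- function(rec, target_fs = 500) {
  fs <- rec$fs
  if (target_fs > fs) stop("parameter error: target_fs must be <= fs")
  if (target_fs == fs) return(rec)
  ratio <- target_fs / fs
  den <- NULL
  for (q in 1:1000) {
    if (abs(ratio * q - round(ratio * q)) < 1e-9) { den <- q; break }
  }
  if (is.null(den))
    stop("parameter error: fs ratio ", format(ratio),
         " is not rational within tolerance")

  n <- ncol(rec$data)
  cutoff <- 0.9 * (target_fs / 2) / (fs / 2)  # fraction of input Nyquist
  n_taps <- max(64L, 2L * ceiling(8 / cutoff))  # keep passband flat at low ratios
  h <- signal::fir1(n_taps, cutoff)
  n_new <- floor((n - 1) * ratio) + 1L
  t_new <- (seq_len(n_new) - 1) / ratio + 1  # positions on the old grid
  old_t <- seq_len(n)
  out <- matrix(0, nrow(rec$data), n_new, dimnames = list(rownames(rec$data), NULL))
  for (i in seq_len(nrow(rec$data))) {
    xf <- filtfilt_padded(h, 1, rec$data[i, ])
    out[i, ] <- stats::approx(old_t, xf, xout = t_new)$y
  }
  ev <- rec$events
  ev$latency <- as.integer(round(ev$latency * ratio))
  ev <- ev[ev$latency < n_new, , drop = FALSE]
  rec$data <- out; rec$fs <- target_fs; rec$events <- ev
  qc_log("resample", fs, " -> ", target_fs, " Hz")
  rec
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering with a Butterworth IIR
#' band-pass of the given design order; the effective magnitude response
#' is squared (effective order doubled) with zero group delay. Channel
#' means are removed before filtering, so DC input maps to exactly zero.
#' Edges are handled by odd-reflection padding.
#'
#' @param rec an [eeg_recording()].
#' @param low,high band edges in Hz (`high` below Nyquist).
#' @param order Butterworth design order (default 2).
#' @return The filtered `eeg_recording`.
#' @export
bandpass_eeg <- function(rec, low = 0.5, high = 30, order = 2) {
  if (low >= high) stop("parameter error: low must be < high")
  if (high >= rec$fs / 2) stop("parameter error: high must be below Nyquist")
  bt <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    x <- x - mean(x)
    rec$data[i, ] <- filtfilt_padded(bt$b, bt$a, x,
                                     pad = round(3 * rec$fs / low))
  }
  qc_log("bandpass", low, "-", high, " Hz order ", order, " zero-phase")
  rec
}

# filtfilt with odd-reflection padding to suppress edge transients
filtfilt_padded <- function(b, a, x, pad = 3 * length(b)) {
  n <- length(x)
  np <- min(n - 1L, max(1L, round(pad)))
  xp <- c(2 * x[1] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  y <- signal::filtfilt(as.numeric(b), as.numeric(a), xp)
  y[(np + 1L):(np + n)]
}

#' Interpolate bad channels
#'
#' Replaces each bad channel by the inverse-distance-weighted (power 2,
#' great-circle distance on the unit sphere) mean of the good channels.
#' A bad channel coincident with a good electrode takes that electrode's
#' signal exactly.
#'
#' @param rec an [eeg_recording()] carrying a montage.
#' @param bad labels of channels to replace (subset of montage labels).
#' @return The `eeg_recording` with bad channels replaced.
#' @export
interpolate_bad_channels <- function(rec, bad) {
  mont <- rec$montage
  if (is.null(mont)) stop("recording has no montage")
  if (!all(bad %in% mont$labels))
    stop("bad channels not in montage: ",
         paste(setdiff(bad, mont$labels), collapse = ", "))
  good <- setdiff(rownames(rec$data), bad)
  good <- intersect(good, mont$labels)
  if (length(good) == 0L) stop("all channels bad; cannot interpolate")
  if (length(good) < 4L) stop("need at least 4 good channels")
  P <- mont$positions
  for (b in bad) {
    cosang <- pmin(1, pmax(-1, P[good, , drop = FALSE] %*% P[b, ]))
    d <- acos(cosang)
    if (any(d < 1e-9)) {
      rec$data[b, ] <- rec$data[good[which.min(d)], ]
    } else {
      w <- 1 / d^2
      w <- w / sum(w)
      rec$data[b, ] <- as.vector(t(w) %*% rec$data[good, , drop = FALSE])
    }
  }
  qc_log("interpolate", "replaced ", length(bad), " channel(s)")
  rec
}

#' Re-reference to the average reference
#'
#' Subtracts, at every sample, the mean over `subset` from every channel.
#' Idempotent when `subset` spans the channels being averaged.
#'
#' @param rec an [eeg_recording()].
#' @param subset channel labels defining the reference (default: all
#'   montage labels, or all rows when no montage is attached).
#' @return The re-referenced `eeg_recording` with `reference = "average"`.
#' @export
rereference_average <- function(rec, subset = NULL) {
  if (is.null(subset))
    subset <- if (!is.null(rec$montage)) rec$montage$labels else rownames(rec$data)
  if (length(subset) == 0L) stop("parameter error: empty reference subset")
  ref <- colMeans(rec$data[subset, , drop = FALSE])
  rec$data <- sweep(rec$data, 2, ref)
  rec$reference <- "average"
  rec
}

#' Epoch a recording and baseline-correct
#'
#' Cuts half-open windows `[window[1], window[2])` seconds around each
#' event of the given label and subtracts, per epoch and channel, the
#' mean over the baseline interval. Epochs whose window exceeds the
#' recording bounds are dropped (with the count logged).
#'
#' @param rec an [eeg_recording()].
#' @param event_label which events to epoch on.
#' @param window epoch window `c(start, end)` in seconds.
#' @param baseline baseline interval `c(start, end)` in seconds (within
#'   `window`).
#' @return An [epoched_eeg()].
#' @export
epoch_and_baseline <- function(rec, event_label = "stimulus",
                               window = c(-0.8, 1.8),
                               baseline = c(-0.8, -0.6)) {
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("parameter error: baseline must lie within the window")
  fs <- rec$fs
  lats <- event_latencies(rec, event_label)
  if (!length(lats)) stop("no events with label '", event_label, "'")
  o1 <- round(window[1] * fs); o2 <- round(window[2] * fs)
  L <- o2 - o1
  n <- ncol(rec$data)
  first <- lats + o1       # 0-based start sample
  ok <- first >= 0L & (first + L) <= n
  if (any(!ok))
    qc_log("epoch", sum(!ok), " epoch(s) dropped (window out of bounds)")
  lats <- lats[ok]
  if (!length(lats)) stop("no epoch fits inside the recording")
  nch <- nrow(rec$data)
  out <- array(0, c(length(lats), nch, L))
  b1 <- round(baseline[1] * fs) - o1 + 1L
  b2 <- round(baseline[2] * fs) - o1
  for (e in seq_along(lats)) {
    seg <- rec$data[, lats[e] + o1 + seq_len(L), drop = FALSE]
    bl <- rowMeans(seg[, b1:b2, drop = FALSE])
    out[e, , ] <- seg - bl
  }
  epoched_eeg(out, fs, window, baseline, labels = rownames(rec$data))
}

#' Run the full EEG cleaning chain
#'
#' Applies, in order: sliding average-artifact subtraction (only when
#' `tr_onset` events are present), resampling, zero-phase band-pass,
#' QRS detection plus pulse-artifact subtraction (only when requested or
#' when the recording condition implies the scanner bore), bad-channel
#' interpolation, and average re-referencing. Stages whose artifacts are
#' absent are skipped cleanly.
#'
#' @param rec an [eeg_recording()].
#' @param ecg optional ECG trace at the original sampling rate.
#' @param target_fs resampling target, Hz.
#' @param band band-pass edges, Hz.
#' @param epochs_per_average see [aas_correct()].
#' @param do_pulse logical or `NULL` (auto: pulse correction inside the
#'   scanner, i.e. conditions `pre_acquisition` and `simultaneous`).
#' @param bad_channels labels to interpolate, if any.
#' @return List with the cleaned `eeg_recording` (`recording`), the
#'   `qrs_detection` (or `NULL`), and a `stages` character vector.
#' @export
clean_eeg <- function(rec, ecg = NULL, target_fs = 500, band = c(0.5, 30),
                      epochs_per_average = 25L, do_pulse = NULL,
                      bad_channels = NULL) {
  stages <- character(0)
  if (any(rec$events$label == "tr_onset")) {
    rec <- aas_correct(rec, epochs_per_average)
    stages <- c(stages, "aas")
  }
  orig_fs <- rec$fs
  rec <- resample_eeg(rec, target_fs)
  stages <- c(stages, "resample")
  rec <- bandpass_eeg(rec, band[1], band[2])
  stages <- c(stages, "bandpass")
  if (is.null(do_pulse))
    do_pulse <- rec$condition %in% c("pre_acquisition", "simultaneous")
  det <- NULL
  if (do_pulse) {
    ecg_r <- NULL
    if (!is.null(ecg)) {
      tmp <- eeg_recording(matrix(ecg, 1), orig_fs)
      ecg_r <- resample_eeg(tmp, target_fs)$data[1, ]
    }
    det <- detect_qrs(rec, ecg = ecg_r)
    rec <- pulse_subtract(rec, det)
    stages <- c(stages, "qrs", "pulse")
  }
  if (length(bad_channels)) {
    rec <- interpolate_bad_channels(rec, bad_channels)
    stages <- c(stages, "interpolate")
  }
  rec <- rereference_average(rec)
  stages <- c(stages, "rereference")
  list(recording = rec, qrs = det, stages = stages)
}
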