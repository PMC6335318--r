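#' Pulse-artifact subtraction with a Gaussian-weighted mean template
#'
#' Removes the ballistocardiogram artifact: around each detected R peak,
#' an artifact epoch spanning `[-0.25, +0.75] * RRmed` (RRmed = median RR
#' interval) is defined, and the template subtracted from epoch `i` is
#' the Gaussian-weighted mean of the `n_neighbors` nearest epochs `j`,
#' with weights `exp(-(i - j)^2 / (2 * gaussian_sd_epochs^2))`. Templates
#' are estimated from the uncorrected data; epochs are processed in peak
#' order and each subtraction window is clipped to start after the
#' previous one, so every sample is corrected at most once. As
#' `gaussian_sd_epochs` grows the template tends to the unweighted moving
#' mean. The template is subtracted as estimated, without per-epoch
#' rescaling.
#'
#' @param rec an [eeg_recording()] (gradient-corrected, bandpassed).
#' @param peaks a [detect_qrs()] result, or a vector of 0-based peak
#'   latencies in samples.
#' @param n_neighbors epochs entering each template.
#' @param gaussian_sd_epochs SD of the Gaussian weights, in epochs.
#' @return The corrected `eeg_recording`.
#' @export
pulse_subtract <- function(rec, peaks, n_neighbors = 20L,
                           gaussian_sd_epochs = 5) {
  lat <- if (inherits(peaks, "qrs_detection")) peaks$peak_latencies
         else as.integer(peaks)
  lat <- sort(lat)
  if (length(lat) < 3L) stop("need at least 3 R peaks")
  fs <- rec$fs
  rr_med <- stats::median(diff(lat)) / fs
  pre <- round(0.25 * rr_med * fs)
  post <- round(0.75 * rr_med * fs)
  L <- pre + post
  n <- ncol(rec$data)
  n_pk <- length(lat)

  starts <- lat - pre + 1L  # 1-based first column of each epoch
  ok <- starts >= 1L & (starts + L - 1L) <= n
  if (any(!ok))
    warning(sum(!ok), " epoch(s) exceed the recording bounds and were skipped")
  nch <- nrow(rec$data)
  E <- array(NA_real_, c(n_pk, nch, L))
  for (i in which(ok))
    E[i, , ] <- rec$data[, starts[i] + 0:(L - 1L), drop = FALSE]

  out <- rec$data
  idx_ok <- which(ok)
  prev_end <- 0L
  for (i in idx_ok) {
    d <- abs(idx_ok - i)
    nb <- idx_ok[order(d)][seq_len(min(n_neighbors, length(idx_ok)))]
    w <- exp(-((nb - i)^2) / (2 * gaussian_sd_epochs^2))
    w <- w / sum(w)
    tmpl <- matrix(0, nch, L)
    for (k in seq_along(nb)) tmpl <- tmpl + w[k] * E[nb[k], , ]
    from <- max(starts[i], prev_end + 1L)
    if (from <= starts[i] + L - 1L) {
      cols <- from:(starts[i] + L - 1L)
      out[, cols] <- out[, cols] - tmpl[, cols - starts[i] + 1L, drop = FALSE]
    }
    prev_end <- starts[i] + L - 1L
  }
  rec$data <- out
  qc_log("pulse", "subtracted templates at ", length(idx_ok), " peaks (RRmed ",
         round(rr_med, 3), " s)")
  rec
}
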