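#' Gradient-artifact removal by sliding average artifact subtraction
#'
#' Removes the TR-periodic MR gradient artifact with the weighted
#' moving-average template approach: for each channel and each TR epoch,
#' the mean over a sliding window of neighbouring TR epochs (centred on
#' the current epoch, truncated at the recording edges) is subtracted.
#' Samples outside any TR epoch are left unchanged. The method assumes a
#' constant TR interval in samples, i.e. clock synchronization between
#' the MR scanner and the EEG amplifier; no sub-sample realignment is
#' performed.
#'
#' @param rec an [eeg_recording()] with `tr_onset` events.
#' @param epochs_per_average number of TR epochs averaged per template
#'   (default 25: 12 before, the current epoch, 12 after).
#' @return The corrected `eeg_recording`.
#' @export
aas_correct <- function(rec, epochs_per_average = 25L) {
  onsets <- event_latencies(rec, "tr_onset")
  n_ep <- length(onsets)
  if (n_ep < 2L) stop("alignment error: need at least 2 tr_onset events")
  iv <- diff(onsets)
  L <- round(stats::median(iv))
  if (any(abs(iv - L) > 1L))
    stop("alignment error: TR interval varies by more than 1 sample (",
         min(iv), "-", max(iv), "); clock synchronization assumption violated")
  if (n_ep < epochs_per_average) {
    if (n_ep < 3L)
      stop("alignment error: fewer than 3 TR epochs; cannot build a template")
    warning("only ", n_ep, " TR epochs; averaging window shrinks from ",
            epochs_per_average, " to ", n_ep)
    epochs_per_average <- n_ep
  }
  half <- (epochs_per_average - 1L) %/% 2L
  n <- ncol(rec$data)
  # drop a trailing epoch that would run past the end
  if (onsets[n_ep] + L > n) { onsets <- onsets[-n_ep]; n_ep <- n_ep - 1L }

  nch <- nrow(rec$data)
  # epochs as an (n_ep x nch*L) matrix so the sliding mean is one cumsum
  E <- matrix(0, n_ep, nch * L)
  for (e in seq_len(n_ep))
    E[e, ] <- as.vector(rec$data[, onsets[e] + seq_len(L)])
  cs <- apply(E, 2, cumsum)
  if (n_ep == 1L) cs <- matrix(cs, nrow = 1L)
  out <- rec$data
  for (e in seq_len(n_ep)) {
    lo <- max(1L, e - half); hi <- min(n_ep, e + half)
    tot <- cs[hi, ] - (if (lo > 1L) cs[lo - 1L, ] else 0)
    tmpl <- tot / (hi - lo + 1L)
    out[, onsets[e] + seq_len(L)] <-
      rec$data[, onsets[e] + seq_len(L)] - matrix(tmpl, nch, L)
  }
  rec$data <- out
  qc_log("aas", "corrected ", n_ep, " TR epochs of ", L, " samples")
  rec
}
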