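#' Multichannel EEG recording
#'
#' The central EEG container: a channels x samples amplitude matrix in
#' microvolts, the sampling rate, event markers, and optionally the
#' montage. Event latencies are 0-based sample indices; time windows
#' throughout the package are half-open `[start, end)` in seconds.
#'
#' @param data numeric matrix, channels x samples, microvolts. Row names
#'   are channel labels.
#' @param fs sampling rate in Hz.
#' @param events data.frame with integer column `latency` (0-based sample)
#'   and character column `label` (`tr_onset`, `stimulus`, `r_peak`, or a
#'   custom label). Defaults to no events.
#' @param montage optional [montage()] describing the channels.
#' @param reference reference description: a channel label or `"average"`.
#' @param condition recording-condition tag: one of `"separate"`,
#'   `"outside"`, `"pre_acquisition"`, `"simultaneous"`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, events = NULL, montage = NULL,
                          reference = "unknown", condition = "separate") {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("eeg_recording: data must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("eeg_recording: fs must be a positive scalar")
  if (is.null(events))
    events <- data.frame(latency = integer(0), label = character(0),
                         stringsAsFactors = FALSE)
  events <- data.frame(latency = as.integer(events$latency),
                       label = as.character(events$label),
                       stringsAsFactors = FALSE)
  n <- ncol(data)
  if (nrow(events) && (any(events$latency < 0L) || any(events$latency >= n)))
    stop("eeg_recording: event latencies must lie in [0, n_samples)")
  if (!is.null(montage)) {
    if (!inherits(montage, "eeg_montage")) stop("montage must be an eeg_montage")
    if (is.null(rownames(data))) rownames(data) <- montage$labels
    if (!all(montage$labels %in% rownames(data)))
      stop("eeg_recording: data rows missing montage labels: ",
           paste(setdiff(montage$labels, rownames(data)), collapse = ", "))
  }
  condition <- match.arg(condition,
                         c("separate", "outside", "pre_acquisition",
                           "simultaneous"))
  structure(list(data = data, fs = fs, events = events, montage = montage,
                 reference = reference, condition = condition),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz (%.1f s), %d events, ref=%s, condition=%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events), x$reference, x$condition))
  invisible(x)
}

#' Event latencies of a given label
#'
#' @param rec an `eeg_recording`.
#' @param label event label to select.
#' @return Integer vector of 0-based sample latencies, sorted.
#' @export
event_latencies <- function(rec, label) {
  sort(rec$events$latency[rec$events$label == label])
}

#' Epoched EEG
#'
#' @param data numeric array, epochs x channels x samples, microvolts.
#' @param fs sampling rate, Hz.
#' @param window `c(start, end)` seconds relative to the event, half-open.
#' @param baseline `c(start, end)` seconds, must lie within `window`.
#' @param labels optional channel labels.
#' @return An object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, fs, window, baseline, labels = NULL) {
  if (length(dim(data)) != 3L) stop("epoched data must be epochs x channels x samples")
  if (baseline[1] < window[1] || baseline[2] > window[2])
    stop("baseline interval must lie within the epoch window")
  structure(list(data = data, fs = fs, window = window, baseline = baseline,
                 labels = labels),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_eeg> %d epochs x %d ch x %d samples @ %g Hz, window [%g, %g) s\n",
              d[1], d[2], d[3], x$fs, x$window[1], x$window[2]))
  invisible(x)
}

#' 4D fMRI volume series
#'
#' @param data numeric 4D array (x, y, z, t), arbitrary MR units.
#' @param tr repetition time in seconds.
#' @param affine 4x4 voxel-to-world transform (must be invertible).
#' @param mask optional logical 3D array.
#' @return An object of class `volume_series`.
#' @export
volume_series <- function(data, tr, affine = diag(4), mask = NULL) {
  if (length(dim(data)) != 4L) stop("volume_series: data must be 4D (x, y, z, t)")
  if (dim(data)[4] < 2L) stop("volume_series: need at least 2 volumes")
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) ||
      abs(det(affine)) < .Machine$double.eps)
    stop("volume_series: affine must be an invertible 4x4 matrix")
  if (!is.null(mask) && !all(dim(mask) == dim(data)[1:3]))
    stop("volume_series: mask must match the spatial grid")
  structure(list(data = data, tr = tr, affine = affine, mask = mask),
            class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume_series> %d x %d x %d x %d, TR %g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  invisible(x)
}

#' Motion parameter series
#'
#' Per-volume rigid-body parameters: three translations in mm and three
#' rotations in radians, as produced by fMRI realignment.
#'
#' @param params numeric matrix, volumes x 6.
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion_params: need 6 columns (3 trans mm, 3 rot rad)")
  colnames(params) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  structure(list(params = params), class = "motion_params")
}
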