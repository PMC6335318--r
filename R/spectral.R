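#' Squared FFT amplitudes per channel
#'
#' Computes `A^2(f)`, the squared single-sided FFT amplitude per channel,
#' on a 0-`fmax` Hz grid. Normalization is such that a pure sinusoid of
#' amplitude `a` centred on a bin contributes `a^2` at that bin
#' (amplitude-squared scaling with window coherent-gain correction).
#' Continuous data are averaged over tapered segments with 50% overlap;
#' epoched data are computed per epoch over the whole epoch and averaged
#' over epochs.
#'
#' @param x an [eeg_recording()], a channels x samples matrix, or an
#'   [epoched_eeg()].
#' @param fs sampling rate (taken from `x` when it carries one).
#' @param fmax upper frequency bound of the analysis grid, Hz.
#' @param window `"hann"` (default) or `"rectangular"`. The rectangular
#'   window makes the single-sided Parseval identity
#'   `sum(A^2) = 2 * var(x)` exact; the Hann taper controls leakage at
#'   the cost of broadband-power calibration.
#' @param segment_s segment length for continuous data, seconds (the
#'   frequency resolution is `1/segment_s`).
#' @return An object of class `spectral_summary`: `labels`, `freqs`,
#'   `a2` (channels x frequencies, square microvolts), `n_segments`,
#'   `fs`, and the window used.
#' @export
fft_sq_amplitude <- function(x, fs = NULL, fmax = 65,
                             window = c("hann", "rectangular"),
                             segment_s = 2) {
  window <- match.arg(window)
  if (inherits(x, "eeg_recording")) { fs <- x$fs; x <- x$data }
  if (inherits(x, "epoched_eeg")) {
    fs0 <- x$fs
    d <- x$data
    segs <- lapply(seq_len(dim(d)[1]), function(e) d[e, , , drop = TRUE])
    if (dim(d)[2] == 1L) segs <- lapply(segs, function(s) matrix(s, 1))
    fs <- fs0
    labels <- x$labels
  } else {
    x <- as.matrix(x)
    if (is.null(fs)) stop("fs must be given for matrix input")
    L <- round(segment_s * fs)
    n <- ncol(x)
    if (n < L) stop("segment shorter than one analysis window (",
                    n, " < ", L, " samples)")
    starts <- seq(1L, n - L + 1L, by = max(1L, L %/% 2L))
    segs <- lapply(starts, function(s) x[, s + 0:(L - 1L), drop = FALSE])
    labels <- rownames(x)
  }
  Lw <- ncol(segs[[1]])
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * seq_len(Lw) / (Lw + 1))
       else rep(1, Lw)
  sw <- sum(w)
  freqs_all <- (seq_len(floor(Lw / 2) + 1L) - 1L) * fs / Lw
  keep <- freqs_all <= fmax
  a2 <- 0
  for (seg in segs) {
    X <- t(stats::mvfft(t(seg * rep(w, each = nrow(seg)))))
    amp <- 2 * Mod(X[, seq_len(sum(keep)), drop = FALSE]) / sw
    amp[, freqs_all[keep] == 0] <- amp[, freqs_all[keep] == 0] / 2
    a2 <- a2 + amp^2
  }
  a2 <- a2 / length(segs)
  rownames(a2) <- labels
  structure(list(labels = labels, freqs = freqs_all[keep], a2 = a2,
                 n_segments = length(segs), fs = fs, window = window),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> %d ch x %d bins (0-%.1f Hz, df %.2f Hz), %d segment(s), %s window\n",
              nrow(x$a2), ncol(x$a2), max(x$freqs),
              x$freqs[2] - x$freqs[1], x$n_segments, x$window))
  invisible(x)
}

#' Mean squared amplitudes in 2 Hz bands around integer frequencies
#'
#' For every integer centre frequency `c` in `centers`, the mean of
#' `A^2(f)` over the bins with `f` in the half-open interval
#' `[c - 1, c + 1)`.
#'
#' @param spec a [fft_sq_amplitude()] result.
#' @param centers integer centre frequencies (default 1-64 Hz, limited
#'   to the available grid).
#' @return The `spectral_summary` with fields `band_centers` and
#'   `band_means` (channels x centres) added.
#' @export
band_means <- function(spec, centers = 1:64) {
  centers <- centers[centers + 1 <= max(spec$freqs) + 1e-9]
  bm <- matrix(NA_real_, nrow(spec$a2), length(centers),
               dimnames = list(spec$labels, centers))
  for (i in seq_along(centers)) {
    sel <- spec$freqs >= centers[i] - 1 & spec$freqs < centers[i] + 1
    if (!any(sel))
      stop("empty band around ", centers[i],
           " Hz: frequency resolution too coarse")
    bm[, i] <- rowMeans(spec$a2[, sel, drop = FALSE])
  }
  spec$band_centers <- centers
  spec$band_means <- bm
  spec
}

#' Mean band power over a centre-frequency range
#'
#' Per-channel mean of the 2 Hz band means over integer centres
#' `lo..hi` inclusive (default the 15-25 Hz range).
#'
#' @param spec a [band_means()] result.
#' @param lo,hi centre-frequency bounds, Hz.
#' @return Named numeric vector, square microvolts per channel.
#' @export
band_mean_range <- function(spec, lo = 15, hi = 25) {
  if (is.null(spec$band_means)) spec <- band_means(spec)
  sel <- spec$band_centers >= lo & spec$band_centers <= hi
  if (!all(lo:hi %in% spec$band_centers))
    stop("band centers do not cover [", lo, ", ", hi, "]")
  v <- rowMeans(spec$band_means[, sel, drop = FALSE])
  names(v) <- spec$labels
  v
}

#' Index of dispersion across electrodes
#'
#' The sample variance (n-1 denominator) over electrodes divided by the
#' mean over electrodes. Zero exactly when all electrodes are equal;
#' scaling all electrodes by `k > 0` scales the index by `k`.
#'
#' @param values per-electrode non-negative scalars (square microvolts).
#' @return The index of dispersion, square microvolts.
#' @export
index_of_dispersion <- function(values) {
  m <- mean(values)
  if (!is.finite(m) || m <= 0)
    stop("undefined statistic: mean of electrode values must be > 0")
  stats::var(values) / m
}

#' Dispersion as a function of centre frequency
#'
#' @param spec a [band_means()] result.
#' @param condition condition tag carried along for reporting.
#' @return An object of class `dispersion_curve`: `band_centers`,
#'   `dispersion` (square microvolts), `condition`.
#' @export
dispersion_curve <- function(spec, condition = "unknown") {
  if (is.null(spec$band_means)) spec <- band_means(spec)
  disp <- apply(spec$band_means, 2, index_of_dispersion)
  structure(list(band_centers = spec$band_centers, dispersion = disp,
                 condition = condition),
            class = "dispersion_curve")
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf("<dispersion_curve> %d centres, condition=%s, 15-25 Hz mean %.3g uV^2\n",
              length(x$band_centers), x$condition,
              mean(x$dispersion[x$band_centers >= 15 & x$band_centers <= 25])))
  invisible(x)
}
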