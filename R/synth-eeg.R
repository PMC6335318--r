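#' Parameters for the synthetic EEG session generator
#'
#' The generator emulates a 10-5 EEG recording in the four recording
#' conditions of an EEG-fMRI quality study: fully separate acquisition,
#' rest in the scanner control room, rest in the bore before image
#' acquisition, and simultaneous recording during image acquisition.
#' The signal model is: 1/f background + band-limited rhythms + 50 Hz
#' line noise + a 15-25 Hz band-limited component with per-channel
#' condition gains (the left-right/amplifier-patterned inhomogeneity) +
#' optional TR-periodic gradient artifact + optional QRS-locked pulse
#' artifact with jittered RR intervals.
#'
#' @param montage an [montage()]; defaults to the packaged 60-channel one.
#' @param fs sampling rate, Hz.
#' @param duration seconds.
#' @param background `list(exponent, rms)`: 1/f^exponent shape and RMS in
#'   microvolts.
#' @param rhythms list of `list(center, bandwidth, rms)` oscillations (Hz,
#'   Hz, microvolts).
#' @param line_noise `list(freq, amplitude)`: mains frequency (Hz) and
#'   sinusoid amplitude (microvolts).
#' @param band `list(lo, hi, rms)`: the condition-gain band-limited
#'   component (Hz, Hz, microvolts RMS at unit gain).
#' @param condition_gain per-channel multiplicative gain on the band
#'   component, or `NULL` for unit gain; see [preset_eeg_params()].
#' @param gradient `NULL`, or `list(tr, n_slices, amplitude, drift)`:
#'   repetition time (s), slices per volume, template RMS (microvolts) and
#'   amplitude drift fraction per minute.
#' @param pulse `NULL`, or `list(hr, sd, scale, jitter)`: mean heart rate
#'   (bpm, must stay below the 110 bpm detector assumption), its SD (bpm),
#'   per-channel template peak scale (microvolts) and epoch-to-epoch
#'   amplitude jitter fraction.
#' @param stim_interval spacing of stimulus markers in seconds (`NULL`
#'   for none).
#' @param condition recording-condition tag.
#' @param keep_components store the per-component channel matrices in the
#'   ground truth (memory-hungry; used by calibration tests).
#' @param seed RNG seed; identical parameters and seed give bit-identical
#'   sessions.
#' @return An object of class `eeg_sim_params`.
#' @export
eeg_sim_params <- function(montage = standard_montage(), fs = 5000,
                           duration = 60,
                           background = list(exponent = 1, rms = 10),
                           rhythms = list(list(center = 10, bandwidth = 2, rms = 4),
                                          list(center = 20, bandwidth = 4, rms = 2)),
                           line_noise = list(freq = 50, amplitude = 2),
                           band = list(lo = 15, hi = 25, rms = 2),
                           condition_gain = NULL,
                           gradient = NULL, pulse = NULL,
                           stim_interval = 3,
                           condition = "separate",
                           keep_components = FALSE, seed = 1) {
  if (!is.null(pulse) && pulse$hr >= 110)
    stop("parameter error: mean heart rate must be below 110 bpm")
  if (!is.null(gradient)) {
    if (gradient$amplitude < 10 * background$rms)
      stop("parameter error: gradient amplitude must be >= 10x background RMS")
    if (duration < 2 * gradient$tr)
      stop("parameter error: duration too short for >= 2 TRs")
  }
  if (!is.null(condition_gain)) {
    if (length(condition_gain) != length(montage$labels))
      stop("parameter error: condition_gain must have one value per channel")
    if (any(condition_gain < 0))
      stop("parameter error: condition_gain must be non-negative")
  }
  structure(list(montage = montage, fs = fs, duration = duration,
                 background = background, rhythms = rhythms,
                 line_noise = line_noise, band = band,
                 condition_gain = condition_gain, gradient = gradient,
                 pulse = pulse, stim_interval = stim_interval,
                 condition = condition, keep_components = keep_components,
                 seed = seed),
            class = "eeg_sim_params")
}

#' Preset generator parameters for the four recording conditions
#'
#' Encodes how the study conditions differ: the gradient artifact exists
#' only during image acquisition; the pulse artifact exists inside the
#' bore (pre-acquisition and simultaneous); the 15-25 Hz channel-gain
#' inhomogeneity grows from outside the scanner to pre-acquisition to
#' acquisition, with opposite left-right sign on the two amplifiers
#' (amplifier-1 left below right, amplifier-2 right below left).
#'
#' @param preset one of `"separate"`, `"outside"`, `"pre_acquisition"`,
#'   `"simultaneous"`.
#' @param montage,fs,duration,seed see [eeg_sim_params()].
#' @param ... further overrides passed to [eeg_sim_params()].
#' @return An `eeg_sim_params`.
#' @export
preset_eeg_params <- function(preset = c("separate", "outside",
                                         "pre_acquisition", "simultaneous"),
                              montage = standard_montage(), fs = 5000,
                              duration = 60, seed = 1, ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    separate        = list(asym = 0.05, band_scale = 1.0, grad = FALSE, puls = FALSE),
    outside         = list(asym = 0.10, band_scale = 1.2, grad = FALSE, puls = FALSE),
    pre_acquisition = list(asym = 0.45, band_scale = 2.0, grad = FALSE, puls = TRUE),
    simultaneous    = list(asym = 1.00, band_scale = 5.0, grad = TRUE,  puls = TRUE))
  gain <- amplifier_band_gain(montage, asym = cfg$asym,
                              scale = cfg$band_scale)
  eeg_sim_params(
    montage = montage, fs = fs, duration = duration,
    condition_gain = gain,
    gradient = if (cfg$grad)
      list(tr = 2.0, n_slices = 36, amplitude = 1000, drift = 0.01) else NULL,
    pulse = if (cfg$puls)
      list(hr = 65, sd = 3, scale = 30, jitter = 0.05) else NULL,
    condition = preset, seed = seed, ...)
}

#' Amplifier-patterned left-right band gain
#'
#' Per-channel gain `scale * (1 + asym * s)` where `s` is -1 for left
#' amplifier-1 and right amplifier-2 electrodes, +1 for their homologues,
#' and 0 on the midline.
#'
#' @param mont an `eeg_montage`.
#' @param asym asymmetry fraction in `[0, 1]`.
#' @param scale overall band-amplitude scale.
#' @return Named numeric vector of gains per label.
#' @export
amplifier_band_gain <- function(mont, asym, scale = 1) {
  s <- setNames(numeric(length(mont$labels)), mont$labels)
  p <- mont$pairs
  left1 <- p$left[p$amplifier == 1L]; right1 <- p$right[p$amplifier == 1L]
  left2 <- p$left[p$amplifier == 2L]; right2 <- p$right[p$amplifier == 2L]
  s[left1] <- -1; s[right1] <- 1
  s[left2] <- 1;  s[right2] <- -1
  scale * (1 + asym * s)
}

# Spectrally shaped Gaussian noise: white noise filtered in the frequency
# domain by `shape(f)` (f in Hz, length n/2+1 one-sided grid), rescaled to
# the requested RMS.
shaped_noise <- function(n, fs, shape, rms) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- seq(0, fs / 2, length.out = floor(n / 2) + 1L)
  h <- shape(f)
  h[1] <- 0  # no DC
  full <- if (n %% 2L == 0L) c(h, rev(h[2:(length(h) - 1L)])) else c(h, rev(h[-1L]))
  y <- Re(stats::fft(X * full, inverse = TRUE)) / n
  sd0 <- stats::sd(y)
  if (sd0 == 0) return(numeric(n))
  y * (rms / sd0)
}

one_over_f_noise <- function(n, fs, exponent, rms) {
  shaped_noise(n, fs, function(f) ifelse(f > 0, f^(-exponent / 2), 0), rms)
}

narrowband_noise <- function(n, fs, center, bandwidth, rms) {
  shaped_noise(n, fs,
               function(f) exp(-(f - center)^2 / (2 * (bandwidth / 2)^2)),
               rms)
}

flatband_noise <- function(n, fs, lo, hi, rms) {
  shaped_noise(n, fs, function(f) as.numeric(f >= lo & f <= hi), rms)
}

# Pulse-artifact morphology: R spike, early undershoot, T-like bump.
pulse_waveform <- function(tau) {
  exp(-(tau / 0.015)^2 / 2) -
    0.35 * exp(-((tau - 0.08) / 0.03)^2 / 2) +
    0.45 * exp(-((tau - 0.30) / 0.07)^2 / 2)
}

#' Generate a synthetic EEG-fMRI session (EEG side)
#'
#' @param params an [eeg_sim_params()].
#' @return A list of class `eeg_session` with elements
#'   \describe{
#'     \item{recording}{the [eeg_recording()] (EEG channels only), with
#'       `tr_onset` and `stimulus` events as applicable;}
#'     \item{ecg}{a synthetic ECG trace (microvolts) sampled at `fs`,
#'       flagged non-EEG and therefore not part of the recording matrix;}
#'     \item{truth}{ground truth: `r_peak_times` (s), `tr_onset_samples`
#'       (0-based), `gradient_template` and `pulse_template` (channels x
#'       samples), `injected_band_gain`, `clean` (the artifact-free
#'       channel matrix), and per-component matrices if
#'       `keep_components`;}
#'     \item{params}{the input parameters.}
#'   }
#' @export
generate_eeg_session <- function(params) {
  stopifnot(inherits(params, "eeg_sim_params"))
  set.seed(params$seed)
  mont <- params$montage
  fs <- params$fs
  n <- round(params$duration * fs)
  nch <- length(mont$labels)
  labels <- mont$labels

  gain <- params$condition_gain
  if (is.null(gain)) gain <- setNames(rep(1, nch), labels)

  line <- params$line_noise$amplitude *
    sin(2 * pi * params$line_noise$freq * seq_len(n) / fs +
        stats::runif(1, 0, 2 * pi))

  clean <- matrix(0, nch, n, dimnames = list(labels, NULL))
  comp <- if (params$keep_components)
    list(background = clean, rhythms = clean, band = clean) else NULL
  for (i in seq_len(nch)) {
    bg <- one_over_f_noise(n, fs, params$background$exponent,
                           params$background$rms)
    rh <- numeric(n)
    for (r in params$rhythms)
      rh <- rh + narrowband_noise(n, fs, r$center, r$bandwidth, r$rms)
    bd <- gain[i] * flatband_noise(n, fs, params$band$lo, params$band$hi,
                                   params$band$rms)
    clean[i, ] <- bg + rh + bd + line
    if (params$keep_components) {
      comp$background[i, ] <- bg; comp$rhythms[i, ] <- rh; comp$band[i, ] <- bd
    }
  }

  data <- clean
  events <- data.frame(latency = integer(0), label = character(0),
                       stringsAsFactors = FALSE)

  # channel profiles for artifact topographies (smooth over the scalp)
  grad_profile <- 1 + 0.3 * mont$positions[, "y"]
  pulse_profile <- 0.6 + 0.4 * (mont$positions[, "y"] + 1) / 2

  truth <- list(injected_band_gain = gain, clean = clean,
                gradient_template = matrix(0, nch, 0),
                pulse_template = matrix(0, nch, 0),
                r_peak_times = numeric(0),
                tr_onset_samples = integer(0))

  if (!is.null(params$gradient)) {
    g <- params$gradient
    L <- round(g$tr * fs)
    if (abs(L - g$tr * fs) > 0.5)
      stop("parameter error: tr * fs must be an integer number of samples")
    f_slice <- g$n_slices / g$tr
    K <- max(1L, min(30L, floor(0.45 * fs / f_slice)))
    tt <- (seq_len(L) - 1L) / fs
    w <- numeric(L)
    ph <- stats::runif(K, 0, 2 * pi)
    for (k in seq_len(K))
      w <- w + (1 / k) * sin(2 * pi * k * f_slice * tt + ph[k])
    w <- w * (g$amplitude / stats::sd(w))
    offset <- round(0.1 * fs)
    n_tr <- (n - offset) %/% L
    if (n_tr < 2L) stop("parameter error: duration too short for >= 2 TRs")
    onsets <- offset + (seq_len(n_tr) - 1L) * L  # 0-based
    tmpl <- outer(grad_profile, w)
    for (e in seq_len(n_tr)) {
      drift <- 1 + g$drift * (onsets[e] / fs / 60)
      idx <- onsets[e] + seq_len(L)  # 1-based data columns
      data[, idx] <- data[, idx] + drift * tmpl
    }
    truth$gradient_template <- tmpl
    truth$tr_onset_samples <- onsets
    events <- rbind(events,
                    data.frame(latency = onsets, label = "tr_onset",
                               stringsAsFactors = FALSE))
  }

  if (!is.null(params$pulse)) {
    p <- params$pulse
    rr_mean <- 60 / p$hr
    rr_sd <- 60 * p$sd / p$hr^2
    times <- numeric(0); t_cur <- 0.4
    repeat {
      if (t_cur > params$duration - 0.4) break
      times <- c(times, t_cur)
      rr <- stats::rnorm(1, rr_mean, rr_sd)
      t_cur <- t_cur + max(rr, 60 / 110)
    }
    tau <- seq(-0.2, 0.6, by = 1 / fs)
    wave <- pulse_waveform(tau)
    tmpl <- outer(p$scale * pulse_profile, wave)
    for (tk in times) {
      s0 <- round(tk * fs) - round(0.2 * fs)  # 0-based start
      idx <- s0 + seq_along(tau)              # 1-based columns
      keep <- idx >= 1L & idx <= n
      amp <- 1 + p$jitter * stats::rnorm(1)
      data[, idx[keep]] <- data[, idx[keep]] + amp * tmpl[, keep]
    }
    truth$pulse_template <- tmpl
    truth$r_peak_times <- times
  }

  # ECG trace: sharp R spikes plus T waves and measurement noise
  ecg <- stats::rnorm(n, sd = 10)
  if (!is.null(params$pulse)) {
    tau <- seq(-0.1, 0.5, by = 1 / fs)
    ecg_wave <- 800 * exp(-(tau / 0.008)^2 / 2) +
      120 * exp(-((tau - 0.3) / 0.06)^2 / 2) -
      150 * exp(-((tau - 0.03) / 0.012)^2 / 2)
    for (tk in truth$r_peak_times) {
      s0 <- round(tk * fs) - round(0.1 * fs)
      idx <- s0 + seq_along(tau)
      keep <- idx >= 1L & idx <= n
      ecg[idx[keep]] <- ecg[idx[keep]] + ecg_wave[keep]
    }
  }

  if (!is.null(params$stim_interval)) {
    st <- seq(2, params$duration - 2, by = params$stim_interval)
    if (length(st))
      events <- rbind(events,
                      data.frame(latency = as.integer(round(st * fs)),
                                 label = "stimulus",
                                 stringsAsFactors = FALSE))
  }
  events <- events[order(events$latency), , drop = FALSE]

  if (params$keep_components) truth$components <- comp
  rec <- eeg_recording(data, fs, events = events, montage = mont,
                       reference = "FCz", condition = params$condition)
  structure(list(recording = rec, ecg = ecg, truth = truth,
                 params = params),
            class = "eeg_session")
}

#' @export
print.eeg_session <- function(x, ...) {
  cat("<eeg_session> condition=", x$params$condition, "\n", sep = "")
  print(x$recording)
  invisible(x)
}
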