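test_that("AAS removes a strictly periodic artifact exactly", {
  rec <- periodic_artifact_recording(n_epochs = 30, L = 100)
  out <- aas_correct(rec, 25)
  on <- event_latencies(rec, "tr_onset")
  inside <- unlist(lapply(on, function(o) o + seq_len(100)))
  expect_lt(max(abs(out$data[, inside])), 1e-9)
  # samples outside any TR epoch untouched
  outside <- setdiff(seq_len(ncol(rec$data)), inside)
  expect_identical(out$data[, outside], rec$data[, outside])
})

test_that("sliding AAS tracks slow amplitude drift better than a global template", {
  L <- 80; n_ep <- 100; n_ch <- 2; lead <- 40
  tmpl <- matrix(sin(2 * pi * seq_len(L) / 16), n_ch, L, byrow = TRUE)
  n <- lead + n_ep * L + lead
  data <- matrix(0, n_ch, n)
  on <- lead + (seq_len(n_ep) - 1L) * L
  for (e in seq_len(n_ep))  # 1% amplitude growth per epoch
    data[, on[e] + seq_len(L)] <- (1 + 0.01 * (e - 1)) * tmpl
  rec <- eeg_recording(data, 500,
                       events = data.frame(latency = on, label = "tr_onset"),
                       condition = "simultaneous")
  out <- aas_correct(rec, 25)
  inside <- unlist(lapply(on, function(o) o + seq_len(L)))
  rms_sliding <- sqrt(mean(out$data[, inside]^2))
  # global mean template, computed independently
  glob <- Reduce(`+`, lapply(seq_len(n_ep), function(e)
    data[, on[e] + seq_len(L)])) / n_ep
  res_glob <- data
  for (e in seq_len(n_ep))
    res_glob[, on[e] + seq_len(L)] <- data[, on[e] + seq_len(L)] - glob
  rms_global <- sqrt(mean(res_glob[, inside]^2))
  expect_lt(rms_sliding, rms_global)
})

test_that("AAS attenuates the gradient artifact by >= 40 dB at slice harmonics", {
  p <- preset_eeg_params("simultaneous", montage = tiny_montage(),
                         fs = 1000, duration = 60, seed = 11)
  s <- generate_eeg_session(p)
  out <- aas_correct(s$recording, 25)
  sp_pre <- fft_sq_amplitude(s$recording$data, fs = 1000, fmax = 450,
                             window = "rectangular")
  sp_post <- fft_sq_amplitude(out$data, fs = 1000, fmax = 450,
                              window = "rectangular")
  harm <- seq(18, 450, by = 18)
  sel <- sapply(sp_pre$freqs, function(f) any(abs(f - harm) < 0.3))
  att_db <- 10 * log10(sum(sp_pre$a2[, sel]) / sum(sp_post$a2[, sel]))
  expect_gte(att_db, 40)
})

test_that("AAS enforces its alignment and window preconditions", {
  rec <- periodic_artifact_recording(n_epochs = 10, L = 100)
  bad <- rec
  bad$events$latency[5] <- bad$events$latency[5] + 3L
  expect_error(aas_correct(bad), "alignment error")
  expect_warning(out <- aas_correct(rec, 25), "shrinks")
  two <- periodic_artifact_recording(n_epochs = 2, L = 100)
  expect_error(suppressWarnings(aas_correct(two, 25)), "fewer than 3")
})

test_that("QRS detection on a clean synthetic ECG is near-perfect", {
  p <- eeg_sim_params(montage = tiny_montage(), fs = 500, duration = 120,
                      pulse = list(hr = 65, sd = 2, scale = 30, jitter = 0.05),
                      stim_interval = NULL, seed = 21,
                      condition = "pre_acquisition")
  s <- generate_eeg_session(p)
  rec <- bandpass_eeg(s$recording, 0.5, 30)
  det <- detect_qrs(rec, ecg = s$ecg)
  sc <- score_qrs(det, s$truth$r_peak_times, 500, tol_s = 0.01)
  expect_gte(sc$sensitivity, 0.99)
  expect_gte(sc$precision, 0.99)
})

test_that("the minimal-distance rule keeps the larger of two close peaks", {
  fs <- 500
  x <- numeric(2 * fs)
  tt <- seq_along(x) / fs
  x <- exp(-((tt - 0.8) / 0.01)^2) + 0.5 * exp(-((tt - 1.1) / 0.01)^2)
  det <- detect_qrs(eeg_recording(matrix(0, 1, length(x)), fs), ecg = x)
  expect_length(det$peak_latencies, 1)
  expect_lt(abs(det$peak_latencies / fs - 0.8), 0.01)
})

test_that("ICA-based and ECG-based detection agree on almost all peaks", {
  p <- preset_eeg_params("pre_acquisition", montage = mid_montage(),
                         fs = 500, duration = 60, seed = 13)
  s <- generate_eeg_session(p)
  rec <- bandpass_eeg(s$recording, 0.5, 30)
  det_ecg <- detect_qrs(rec, ecg = s$ecg)
  det_ica <- detect_qrs(rec)
  expect_equal(det_ica$source, "ica")
  agree <- score_qrs(det_ica, det_ecg$peak_latencies / 500, 500, tol_s = 0.01)
  expect_gte(agree$sensitivity, 0.99)
  expect_gte(agree$precision, 0.99)
})

test_that("identical pulse epochs are removed exactly", {
  fs <- 250; n <- 30 * fs
  tau <- seq(-0.2, 0.6, by = 1 / fs)
  wave <- eegfmriqc:::pulse_waveform(tau)
  peaks <- seq(2 * fs, n - 2 * fs, by = fs)  # 1 s apart, 0-based
  data <- matrix(0, 2, n)
  for (pk in peaks) {
    idx <- pk - round(0.2 * fs) + seq_along(tau)
    data[, idx] <- data[, idx] + rbind(10 * wave, 20 * wave)
  }
  rec <- eeg_recording(data, fs)
  out <- pulse_subtract(rec, peaks)
  win <- unlist(lapply(peaks[3:(length(peaks) - 3)],
                       function(pk) pk + seq(-0.1 * fs, 0.3 * fs)))
  expect_lt(max(abs(out$data[, win])), 1e-9)
})

test_that("an infinitely wide Gaussian reduces to the unweighted moving mean", {
  set.seed(4)
  fs <- 250; n <- 20 * fs
  data <- matrix(rnorm(2 * n), 2, n)
  peaks <- seq(fs, n - 2 * fs, by = fs)
  rec <- eeg_recording(data, fs)
  out <- pulse_subtract(rec, peaks, n_neighbors = 5, gaussian_sd_epochs = 1e9)
  # brute-force unweighted moving mean with the same windows and clipping
  rr <- median(diff(peaks)) / fs
  pre <- round(0.25 * rr * fs); post <- round(0.75 * rr * fs); L <- pre + post
  man <- data
  prev_end <- 0L
  for (i in seq_along(peaks)) {
    d <- abs(seq_along(peaks) - i)
    nb <- seq_along(peaks)[order(d)][1:5]
    tm <- Reduce(`+`, lapply(nb, function(j)
      data[, (peaks[j] - pre + 1):(peaks[j] + post), drop = FALSE])) / 5
    st <- peaks[i] - pre + 1L
    from <- max(st, prev_end + 1L)
    cols <- from:(st + L - 1L)
    man[, cols] <- man[, cols] - tm[, cols - st + 1L, drop = FALSE]
    prev_end <- st + L - 1L
  }
  expect_equal(out$data, man, tolerance = 1e-12)
})

test_that("pulse subtraction reduces QRS-locked artifact variance by >= 80%", {
  p <- preset_eeg_params("pre_acquisition", montage = mid_montage(),
                         fs = 500, duration = 60, seed = 3)
  s <- generate_eeg_session(p)
  rec <- bandpass_eeg(s$recording, 0.5, 30)
  clean <- bandpass_eeg(eeg_recording(s$truth$clean, 500), 0.5, 30)
  det <- detect_qrs(rec, ecg = s$ecg)
  out <- suppressWarnings(pulse_subtract(rec, det))
  fs <- 500
  idx <- unlist(lapply(s$truth$r_peak_times, function(tk)
    round(tk * fs) + seq(-0.1 * fs, 0.3 * fs)))
  idx <- idx[idx >= 1 & idx <= ncol(rec$data)]
  v_before <- mean((rec$data[, idx] - clean$data[, idx])^2)
  v_after <- mean((out$data[, idx] - clean$data[, idx])^2)
  expect_gte(1 - v_after / v_before, 0.80)
})

test_that("resampling preserves amplitude, identity, and event latencies", {
  fs <- 5000
  tt <- seq_len(2 * fs) / fs
  x <- matrix(sin(2 * pi * 10 * tt), 1)
  rec <- eeg_recording(x, fs,
                       events = data.frame(latency = 5000L, label = "stimulus"))
  out <- resample_eeg(rec, 500)
  mid <- 200:800
  amp <- sqrt(2 * mean(out$data[1, mid]^2))
  expect_lt(abs(amp - 1), 0.01)
  expect_equal(out$events$latency, 500L)
  expect_equal(out$fs, 500)
  expect_identical(resample_eeg(rec, 5000), rec)
})

test_that("zero-phase Butterworth band-pass has the expected response", {
  fs <- 500
  tt <- seq_len(10 * fs) / fs
  mk <- function(f) eeg_recording(matrix(sin(2 * pi * f * tt), 1), fs)
  mid <- (2 * fs):(8 * fs)
  g10 <- sqrt(2 * mean(bandpass_eeg(mk(10))$data[1, mid]^2))
  expect_gte(g10, 0.95); expect_lte(g10, 1.0 + 1e-6)
  g60 <- sqrt(2 * mean(bandpass_eeg(mk(60))$data[1, mid]^2))
  expect_lt(g60, 0.5)
  dc <- bandpass_eeg(eeg_recording(matrix(7.3, 1, 5 * fs), fs))
  expect_lt(max(abs(dc$data)), 1e-6)
  expect_error(bandpass_eeg(mk(10), low = 30, high = 20), "low must be <")
})

test_that("bad-channel interpolation is a spatial weighted mean", {
  mont <- standard_montage()
  n <- 100
  s <- sin(seq_len(n) / 5)
  # identical signal everywhere -> interpolation reproduces it
  data <- matrix(rep(s, each = 60), 60, dimnames = list(mont$labels, NULL))
  rec <- eeg_recording(data, 100, montage = mont)
  out <- interpolate_bad_channels(rec, "C3")
  expect_equal(out$data["C3", ], s, tolerance = 1e-12)
  # leave-one-out on a smooth spatial field
  f <- 2 + mont$positions[, "y"] + 0.5 * mont$positions[, "z"]
  data2 <- outer(f, s)
  rownames(data2) <- mont$labels
  rec2 <- eeg_recording(data2, 100, montage = mont)
  est <- vapply(mont$labels, function(ch)
    interpolate_bad_channels(rec2, ch)$data[ch, which.max(s)], numeric(1))
  truth <- f * max(s)
  expect_gte(cor(est, truth), 0.95)
  expect_error(interpolate_bad_channels(rec, mont$labels), "all channels bad")
})

test_that("average re-referencing is exact and idempotent", {
  set.seed(6)
  mont <- tiny_montage()
  data <- matrix(rnorm(13 * 200), 13, dimnames = list(mont$labels, NULL))
  rec <- eeg_recording(data, 100, montage = mont)
  out <- rereference_average(rec)
  expect_lt(max(abs(colMeans(out$data))), 1e-9)
  expect_equal(rereference_average(out)$data, out$data, tolerance = 1e-12)
  expect_equal(out$reference, "average")
  # full vs subset reference differ by a per-sample constant
  sub <- rereference_average(rec, subset = c("C3", "C4", "Cz"))
  diffs <- out$data - sub$data
  expect_lt(max(apply(diffs, 2, function(col) diff(range(col)))), 1e-9)
})

test_that("epoching is half-open, baseline-exact, and drops bad epochs", {
  fs <- 500
  n <- 10 * fs
  rec <- eeg_recording(matrix(rnorm(2 * n), 2), fs,
                       events = data.frame(latency = c(100L, 2500L, 4000L),
                                           label = "stimulus"))
  ep <- epoch_and_baseline(rec)  # first event cannot fit the -0.8 s window
  expect_equal(dim(ep$data)[1], 2)
  expect_equal(dim(ep$data)[3], 1300)  # 2.6 s x 500 Hz, half-open
  b1 <- 1; b2 <- 100
  blm <- apply(ep$data[, , b1:b2, drop = FALSE], c(1, 2), mean)
  expect_lt(max(abs(blm)), 1e-9)
  const <- eeg_recording(matrix(5, 1, n), fs,
                         events = data.frame(latency = 2500L, label = "stimulus"))
  expect_lt(max(abs(epoch_and_baseline(const)$data)), 1e-12)
})

test_that("the cleaning pipeline skips artifact stages that do not apply", {
  p <- preset_eeg_params("outside", montage = tiny_montage(), fs = 1000,
                         duration = 10, seed = 2)
  s <- generate_eeg_session(p)
  res <- clean_eeg(s$recording, target_fs = 500)
  expect_false(any(c("aas", "pulse") %in% res$stages))
  expect_true(all(c("resample", "bandpass", "rereference") %in% res$stages))
  expect_null(res$qrs)
  expect_equal(res$recording$fs, 500)
})
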