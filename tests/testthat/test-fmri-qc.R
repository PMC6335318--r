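test_that("TSNR is mean over sample SD, with invalid-voxel handling", {
  arr <- array(0, c(2, 2, 2, 3))
  arr[1, 1, 1, ] <- c(1, 2, 3)
  arr[2, 1, 1, ] <- 5  # constant series
  vs <- volume_series(arr, tr = 2)
  ts <- tsnr_map(vs)
  expect_equal(ts$values[1, 1, 1], 2)  # mean 2 / sample sd 1
  expect_false(ts$valid_mask[2, 1, 1])
  expect_true(is.na(ts$values[2, 1, 1]))
})

test_that("TSNR is exactly invariant to positive rescaling", {
  set.seed(20)
  arr <- array(rnorm(6 * 6 * 3 * 10, mean = 100, sd = 5), c(6, 6, 3, 10))
  t1 <- tsnr_map(volume_series(arr, tr = 2))
  t2 <- tsnr_map(volume_series(arr * 2, tr = 2))  # power of two: exact
  expect_identical(t1$values, t2$values)
})

test_that("compartment metrics are masked summaries with a GM/WM ratio", {
  s <- generate_fmri_session(shape = c(16, 16, 8), n_vols = 60, seed = 21)
  ts <- tsnr_map(s$volumes)
  cm <- compartment_metrics(ts, s$masks[c("gm", "wm", "csf")])
  # oracle: brute-force masked mean
  for (tis in c("gm", "wm", "csf")) {
    sel <- s$masks[[tis]] & ts$valid_mask
    expect_equal(cm$mean[cm$tissue == tis], mean(ts$values[sel]))
    expect_equal(cm$median[cm$tissue == tis], median(ts$values[sel]))
  }
  expect_equal(attr(cm, "gm_wm_ratio"),
               cm$mean[cm$tissue == "gm"] / cm$mean[cm$tissue == "wm"])
  # GM noise 2x WM at equal baseline -> ratio about 0.5
  s2 <- generate_fmri_session(shape = c(16, 16, 8), n_vols = 200,
                              tissue_spec = list(
                                csf = list(baseline = 1000, sd = 20),
                                wm = list(baseline = 1000, sd = 20),
                                gm = list(baseline = 1000, sd = 40)),
                              drift = 0, seed = 22)
  cm2 <- compartment_metrics(tsnr_map(s2$volumes), s2$masks[c("gm", "wm")])
  expect_lt(abs(attr(cm2, "gm_wm_ratio") - 0.5), 0.025)
  expect_error(compartment_metrics(ts, list(a = s$masks$gm, b = s$masks$gm)),
               "disjoint")
})

test_that("uniform TSNR gives equal tissue means and unit ratio", {
  vals <- array(20, c(8, 8, 4))
  ts <- list(values = vals, valid_mask = array(TRUE, c(8, 8, 4)))
  m1 <- array(FALSE, c(8, 8, 4)); m1[1:4, , ] <- TRUE
  m2 <- !m1
  cm <- compartment_metrics(ts, list(gm = m1, wm = m2))
  expect_true(all(cm$mean == 20))
  expect_equal(attr(cm, "gm_wm_ratio"), 1)
})

test_that("Gaussian smoothing preserves constants, mass, and its FWHM", {
  vol <- array(3.3, c(10, 10, 6))
  aff <- diag(c(3, 3, 3, 1))
  sm <- gaussian_smooth(vol, aff, fwhm_mm = 8)
  expect_lt(max(abs(sm - 3.3)), 1e-9)
  imp <- array(0, c(21, 21, 21))
  imp[11, 11, 11] <- 1
  smi <- gaussian_smooth(imp, aff, fwhm_mm = 8)
  expect_lt(abs(sum(smi) - 1), 1e-6)
  prof <- smi[, 11, 11]
  half <- max(prof) / 2
  above <- which(prof >= half)
  # linear interpolation of the half crossings, in mm
  lo <- min(above); hi <- max(above)
  f1 <- lo - 1 + (half - prof[lo - 1]) / (prof[lo] - prof[lo - 1])
  f2 <- hi + (prof[hi] - half) / (prof[hi] - prof[hi + 1])
  fwhm_meas <- (f2 - f1) * 3
  expect_lt(abs(fwhm_meas - 8), 1.5)
})

test_that("cluster labelling uses 18-connectivity", {
  a <- array(FALSE, c(4, 4, 4))
  a[1, 1, 1] <- TRUE; a[2, 2, 1] <- TRUE   # edge neighbours
  cl <- eegfmriqc:::label_clusters(a)
  expect_length(cl$sizes, 1)
  b <- array(FALSE, c(4, 4, 4))
  b[1, 1, 1] <- TRUE; b[2, 2, 2] <- TRUE   # corner neighbours
  cl2 <- eegfmriqc:::label_clusters(b)
  expect_length(cl2$sizes, 2)
})

make_tsnr_set <- function(n_sub, effect = 0, seed = 1, shape = c(12, 12, 6),
                          n_vols = 60) {
  lapply(seq_len(n_sub), function(s) {
    ss <- generate_fmri_session(
      shape = shape, n_vols = n_vols, seed = seed * 100 + s,
      condition_effect = if (effect > 0)
        list(condition = "simultaneous", factor = effect,
             region = "posterior") else NULL,
      condition = if (effect > 0) "simultaneous" else "separate")
    list(img = tsnr_map(ss$volumes), sess = ss)
  })
}

test_that("identical condition images give an empty cluster list", {
  set.seed(23)
  imgs <- lapply(1:5, function(s) {
    arr <- array(rnorm(10 * 10 * 5 * 30, 100, 5), c(10, 10, 5, 30))
    tsnr_map(volume_series(arr, tr = 2))
  })
  res <- paired_group_contrast(imgs, imgs)
  expect_equal(nrow(res$a_gt_b), 0)
  expect_equal(nrow(res$b_gt_a), 0)
  expect_equal(res$n_perm_used, 32)
})

test_that("an injected regional TSNR deficit is recovered as a cluster", {
  n_sub <- 5
  sep <- make_tsnr_set(n_sub, effect = 0, seed = 3)
  sim <- make_tsnr_set(n_sub, effect = 1.5, seed = 7)
  mask <- sep[[1]]$sess$masks$brain
  region <- sim[[1]]$sess$truth$effect_region
  aff <- sep[[1]]$img$affine
  smooth_img <- function(x) {
    v <- x$img$values; v[!x$img$valid_mask] <- 0
    x$img$values <- gaussian_smooth(v, aff, fwhm_mm = 8)
    x$img$valid_mask[] <- TRUE
    x$img
  }
  res <- paired_group_contrast(lapply(sep, smooth_img),
                               lapply(sim, smooth_img), mask = mask)
  expect_gt(nrow(res$a_gt_b), 0)      # separate > simultaneous inside region
  sig <- res$a_gt_b[res$a_gt_b$p_fwe <= 0.05, , drop = FALSE]
  expect_gt(nrow(sig), 0)
  expect_equal(min(res$a_gt_b$p_fwe), 1 / 32)
  # overlap of the recovered cluster(s) with the injected region
  lab <- res$cluster_masks$a_gt_b
  rec_vox <- lab > 0
  expect_gte(sum(rec_vox & region) / sum(region), 0.8)
  # nothing significant in the opposite direction
  expect_equal(sum(res$b_gt_a$p_fwe <= 0.05), 0)
})

test_that("sign-flip cluster inference is valid under a global null", {
  set.seed(24)
  reps <- 100
  fp <- logical(reps)
  dm <- c(8, 8, 4); nv <- 20
  for (i in seq_len(reps)) {
    a <- lapply(1:5, function(s)
      tsnr_map(volume_series(array(rnorm(prod(dm) * nv, 100, 5), c(dm, nv)),
                             tr = 2)))
    b <- lapply(1:5, function(s)
      tsnr_map(volume_series(array(rnorm(prod(dm) * nv, 100, 5), c(dm, nv)),
                             tr = 2)))
    res <- paired_group_contrast(a, b)
    fp[i] <- any(c(res$a_gt_b$p_fwe, res$b_gt_a$p_fwe) <= 0.05)
  }
  expect_lte(mean(fp), 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("subjects missing a condition are rejected", {
  arr <- array(rnorm(8 * 8 * 4 * 20, 100, 5), c(8, 8, 4, 20))
  img <- tsnr_map(volume_series(arr, tr = 2))
  expect_error(paired_group_contrast(list(img, img), list(img)),
               "both conditions")
})
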