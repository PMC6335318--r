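#' Generate a synthetic fMRI session with known TSNR ground truth
#'
#' Builds a concentric-ellipsoid head phantom (CSF core, WM between, GM
#' shell), gives each voxel the series
#' `baseline * (1 + drift * t/T) + noise`, with tissue-specific noise SD,
#' and records the true TSNR field `baseline / sd` per voxel. A
#' `condition_effect` multiplies the noise SD inside a stated region for
#' one recording condition, emulating a regional TSNR change between
#' separate and simultaneous acquisition. A slow-random-walk motion trace
#' is generated alongside.
#'
#' @param shape spatial grid `c(nx, ny, nz)`, at least `c(8, 8, 4)`.
#' @param n_vols number of volumes (>= 20).
#' @param tr repetition time, seconds.
#' @param tissue_spec named list per tissue (`csf`, `wm`, `gm`) of
#'   `list(baseline, sd)` in arbitrary MR units.
#' @param drift linear signal drift over the whole run, as a fraction.
#' @param condition_effect `NULL` or `list(condition, factor, region)`:
#'   noise-SD multiplier applied inside `region` (a logical 3D array, or
#'   `"posterior"` for the posterior third of the phantom) when
#'   `condition` matches.
#' @param condition recording-condition tag for this run.
#' @param motion `list(step_sd, base)`: random-walk step SD (mm) and mean
#'   step size of the translation trace.
#' @param voxel_mm isotropic voxel size, mm (sets the affine).
#' @param seed RNG seed.
#' @return A list of class `fmri_session`: `volumes` (a
#'   [volume_series()]), `masks` (logical arrays `gm`, `wm`, `csf`,
#'   `brain`), `truth` (`true_tsnr` array with `Inf` where sd is 0,
#'   `effect_region`, `true_motion` a [motion_params()]), and the
#'   parameters used.
#' @export
generate_fmri_session <- function(shape = c(24, 24, 12), n_vols = 100,
                                  tr = 2.0,
                                  tissue_spec = list(
                                    csf = list(baseline = 600, sd = 50),
                                    wm = list(baseline = 900, sd = 15),
                                    gm = list(baseline = 1000, sd = 25)),
                                  drift = 0.01,
                                  condition_effect = NULL,
                                  condition = "separate",
                                  motion = list(step_sd = 0.02, base = 0.08),
                                  voxel_mm = 3, seed = 1) {
  if (length(shape) != 3L || any(shape < c(8, 8, 4)))
    stop("spec error: shape must be at least 8 x 8 x 4")
  if (n_vols < 20L) stop("spec error: need at least 20 volumes")
  set.seed(seed)

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  rx <- nx / 2 - 0.5; ry <- ny / 2 - 0.5; rz <- nz / 2 - 0.5
  gx <- ((1:nx) - cx) / rx; gy <- ((1:ny) - cy) / ry; gz <- ((1:nz) - cz) / rz
  r <- sqrt(outer(outer(gx^2, gy^2, `+`), gz^2, `+`))

  csf <- r < 0.25
  wm <- r >= 0.25 & r < 0.7
  gm <- r >= 0.7 & r <= 1.0
  brain <- r <= 1.0
  if (any(csf & wm) || any(wm & gm) || any(csf & gm))
    stop("spec error: overlapping tissue definitions")

  baseline <- array(0, shape); sdmap <- array(0, shape)
  for (tis in c("csf", "wm", "gm")) {
    m <- get(tis)
    baseline[m] <- tissue_spec[[tis]]$baseline
    sdmap[m] <- tissue_spec[[tis]]$sd
  }

  region <- array(FALSE, shape)
  if (!is.null(condition_effect)) {
    reg <- condition_effect$region
    if (is.character(reg) && reg == "posterior") {
      region[, 1:floor(ny / 3), ] <- TRUE  # posterior = low y
      region <- region & brain
    } else region <- reg & brain
    if (identical(condition, condition_effect$condition))
      sdmap[region] <- sdmap[region] * condition_effect$factor
  }

  true_tsnr <- array(Inf, shape)
  pos <- sdmap > 0
  true_tsnr[pos] <- baseline[pos] / sdmap[pos]
  true_tsnr[baseline == 0 & sdmap == 0] <- 0
  degenerate <- any(brain & sdmap == 0)
  if (degenerate)
    warning("degenerate series: zero noise SD inside the phantom; true TSNR is Inf there")

  tfrac <- (seq_len(n_vols) - 1) / max(1, n_vols - 1)
  nvox <- prod(shape)
  data <- array(0, c(shape, n_vols))
  bvec <- as.vector(baseline); svec <- as.vector(sdmap)
  for (v in seq_len(n_vols)) {
    vol <- bvec * (1 + drift * tfrac[v]) + stats::rnorm(nvox, sd = 1) * svec
    data[, , , v] <- vol
  }

  aff <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
  aff[1:3, 4] <- -voxel_mm * c(cx, cy, cz)
  vs <- volume_series(data, tr = tr, affine = aff, mask = brain)

  steps <- matrix(stats::rnorm(n_vols * 3, sd = motion$step_sd / sqrt(3)),
                  n_vols, 3)
  steps[1, ] <- 0
  scale_to <- motion$base / sqrt(3)
  steps[-1, ] <- steps[-1, ] + scale_to
  mp <- motion_params(cbind(apply(steps, 2, cumsum), matrix(0, n_vols, 3)))

  structure(list(volumes = vs,
                 masks = list(gm = gm, wm = wm, csf = csf, brain = brain),
                 truth = list(true_tsnr = true_tsnr,
                              effect_region = region,
                              baseline = baseline, sd = sdmap,
                              true_motion = mp),
                 condition = condition,
                 params = list(shape = shape, n_vols = n_vols, tr = tr,
                               tissue_spec = tissue_spec, drift = drift,
                               condition_effect = condition_effect,
                               motion = motion, voxel_mm = voxel_mm,
                               seed = seed)),
            class = "fmri_session")
}

#' @export
print.fmri_session <- function(x, ...) {
  cat("<fmri_session> condition=", x$condition, "\n", sep = "")
  print(x$volumes)
  invisible(x)
}
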