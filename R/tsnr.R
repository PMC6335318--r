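#' Temporal signal-to-noise ratio map
#'
#' Per voxel, the temporal mean divided by the sample (n-1) temporal
#' standard deviation. Voxels with zero standard deviation are marked
#' invalid and excluded from all downstream statistics. The map is
#' invariant to rescaling the series by any positive factor.
#'
#' @param vs a [volume_series()].
#' @param condition recording-condition tag carried along.
#' @param run run identifier carried along.
#' @return An object of class `tsnr_image`: `values` (3D array, `NA` at
#'   invalid voxels), `valid_mask`, `affine`, `condition`, `run`.
#' @export
tsnr_map <- function(vs, condition = "unknown", run = 1L) {
  d <- vs$data
  dm <- dim(d)
  nt <- dm[4]
  if (nt < 2L) stop("need at least 2 volumes")
  m <- matrix(d, prod(dm[1:3]), nt)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (nt - 1))
  val <- rep(NA_real_, length(mu))
  ok <- sdv > 0
  val[ok] <- mu[ok] / sdv[ok]
  values <- array(val, dm[1:3])
  valid <- array(ok, dm[1:3])
  if (!is.null(vs$mask)) valid <- valid & vs$mask
  structure(list(values = values, valid_mask = valid, affine = vs$affine,
                 condition = condition, run = run),
            class = "tsnr_image")
}

#' @export
print.tsnr_image <- function(x, ...) {
  v <- x$values[x$valid_mask]
  cat(sprintf("<tsnr_image> %s, %d valid voxels, median TSNR %.1f\n",
              paste(dim(x$values), collapse = "x"), sum(x$valid_mask),
              stats::median(v)))
  invisible(x)
}

#' Tissue-compartment TSNR metrics
#'
#' Mean and median TSNR per tissue compartment over valid voxels, plus
#' the grey/white ratio of means as a global-influence summary. Empty
#' masks give `NaN` with a warning. Condition differences of these
#' metrics are what [percentile_bootstrap_diff()] consumes.
#'
#' @param tsnr a [tsnr_map()] result.
#' @param masks named list of disjoint logical 3D arrays (typically
#'   `gm`, `wm`, `csf`).
#' @return A data.frame with rows per tissue (`mean`, `median`,
#'   `n_voxels`) and attribute `"gm_wm_ratio"`.
#' @export
compartment_metrics <- function(tsnr, masks) {
  comb <- Reduce(`+`, lapply(masks, function(m) as.integer(m)))
  if (any(comb > 1L)) stop("tissue masks must be disjoint")
  rows <- lapply(names(masks), function(nm) {
    sel <- masks[[nm]] & tsnr$valid_mask
    v <- tsnr$values[sel]
    if (!length(v)) {
      warning("empty mask for tissue '", nm, "'")
      return(data.frame(tissue = nm, mean = NaN, median = NaN, n_voxels = 0L))
    }
    data.frame(tissue = nm, mean = mean(v), median = stats::median(v),
               n_voxels = length(v))
  })
  out <- do.call(rbind, rows)
  ratio <- NA_real_
  if (all(c("gm", "wm") %in% out$tissue))
    ratio <- out$mean[out$tissue == "gm"] / out$mean[out$tissue == "wm"]
  attr(out, "gm_wm_ratio") <- ratio
  out
}

#' Separable Gaussian smoothing of a volume
#'
#' Gaussian kernel specified by its full width at half maximum in mm,
#' applied separably along each axis with `sd = fwhm / (2 sqrt(2 ln 2))`
#' converted to voxel units through the affine. Edges are handled by
#' renormalizing the truncated kernel, so a constant volume is exactly
#' preserved and interior mass is conserved.
#'
#' @param vol 3D array.
#' @param affine 4x4 affine giving the voxel sizes.
#' @param fwhm_mm kernel FWHM in mm (scalar or per-axis).
#' @return The smoothed 3D array.
#' @export
gaussian_smooth <- function(vol, affine = diag(4), fwhm_mm = 8) {
  vox <- sqrt(colSums(affine[1:3, 1:3]^2))
  fwhm_mm <- rep(fwhm_mm, length.out = 3)
  sd_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / vox
  out <- vol
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(-half:half, sd = s)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution along one axis with edge renormalization
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  half <- (length(k) - 1L) %/% 2L
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, dp[1], dp[2] * dp[3])
  n <- dp[1]
  res <- matrix(0, n, ncol(m))
  wsum <- numeric(n)
  for (j in seq_along(k)) {
    off <- j - half - 1L
    src <- (1:n) + off
    okrows <- src >= 1L & src <= n
    res[okrows, ] <- res[okrows, ] + k[j] * m[src[okrows], , drop = FALSE]
    wsum[okrows] <- wsum[okrows] + k[j]
  }
  res <- res / wsum
  out <- array(res, dp)
  aperm(out, order(perm))
}
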