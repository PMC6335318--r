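#' Project a montage to the 2D scalp plane
#'
#' Azimuthal equidistant projection with the vertex (Cz) at the origin
#' and the nasion pointing up: the projected radius equals the angular
#' distance from the vertex, so electrodes at equal arc from Cz map to
#' equal radii, and left-right mirrored electrodes map to x-mirrored
#' coordinates.
#'
#' @param mont an `eeg_montage` (unit-sphere positions).
#' @return Matrix (n x 2, columns `x`, `y`) of projected positions in
#'   radians, rownames = labels.
#' @export
project_montage <- function(mont) {
  P <- mont$positions
  th <- acos(pmin(1, pmax(-1, P[, 3])))
  r2 <- sqrt(P[, 1]^2 + P[, 2]^2)
  out <- cbind(x = ifelse(r2 > 0, th * P[, 1] / r2, 0),
               y = ifelse(r2 > 0, th * P[, 2] / r2, 0))
  rownames(out) <- mont$labels
  out
}

#' Topographic interpolation of per-electrode values
#'
#' Inverse-distance-weighted (power 2) interpolation of per-electrode
#' values on the projected scalp plane, exact at the electrode
#' positions, masked outside the convex hull of the electrodes.
#' Optionally the log10 of the values is mapped (requires strictly
#' positive inputs).
#'
#' @param values named per-electrode values.
#' @param mont an `eeg_montage`.
#' @param scale `"log10"` or `"linear"`.
#' @param grid_n grid resolution per axis.
#' @return An object of class `topo_map`: `grid_x`, `grid_y`, `z`
#'   (grid_n x grid_n, `NA` outside the hull), `electrodes` (projected
#'   positions), `values` (as mapped), `scale`.
#' @export
topomap <- function(values, mont, scale = c("log10", "linear"),
                    grid_n = 64L) {
  scale <- match.arg(scale)
  labs <- intersect(mont$labels, names(values))
  if (!length(labs)) stop("no electrode values match the montage")
  v <- values[labs]
  if (scale == "log10") {
    if (any(v <= 0))
      stop("log scale requires positive values; offending electrode(s): ",
           paste(labs[v <= 0], collapse = ", "))
    v <- log10(v)
  }
  pos <- project_montage(mont)[labs, , drop = FALSE]
  gx <- seq(min(pos[, 1]), max(pos[, 1]), length.out = grid_n)
  gy <- seq(min(pos[, 2]), max(pos[, 2]), length.out = grid_n)
  hull <- grDevices::chull(pos)
  hx <- pos[hull, 1]; hy <- pos[hull, 2]
  z <- matrix(NA_real_, grid_n, grid_n)
  for (i in seq_len(grid_n)) for (j in seq_len(grid_n)) {
    if (!point_in_polygon(gx[i], gy[j], hx, hy)) next
    d2 <- (pos[, 1] - gx[i])^2 + (pos[, 2] - gy[j])^2
    if (any(d2 < 1e-12)) z[i, j] <- v[which.min(d2)]
    else {
      w <- 1 / d2
      z[i, j] <- sum(w * v) / sum(w)
    }
  }
  structure(list(grid_x = gx, grid_y = gy, z = z, electrodes = pos,
                 values = v, scale = scale),
            class = "topo_map")
}

# ray-crossing point-in-polygon test (boundary counts as inside)
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-edge check
    dx <- vx[j] - vx[i]; dy <- vy[j] - vy[i]
    tproj <- if (dx == 0 && dy == 0) 0 else
      ((px - vx[i]) * dx + (py - vy[i]) * dy) / (dx^2 + dy^2)
    tproj <- min(1, max(0, tproj))
    ex <- vx[i] + tproj * dx; ey <- vy[i] + tproj * dy
    if ((px - ex)^2 + (py - ey)^2 < 1e-18) return(TRUE)
    if ((vy[i] > py) != (vy[j] > py)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' @export
print.topo_map <- function(x, ...) {
  cat(sprintf("<topo_map> %dx%d grid, %d electrodes, %s scale\n",
              length(x$grid_x), length(x$grid_y), nrow(x$electrodes),
              x$scale))
  invisible(x)
}

#' @export
plot.topo_map <- function(x, main = "", ...) {
  graphics::image(x$grid_x, x$grid_y, x$z, asp = 1, axes = FALSE,
                  xlab = "", ylab = "", main = main,
                  col = grDevices::hcl.colors(64, "Viridis"), ...)
  graphics::points(x$electrodes[, 1], x$electrodes[, 2], pch = 20,
                   cex = 0.5)
  invisible(x)
}
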