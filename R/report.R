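#' Multi-condition topographic comparison report
#'
#' The reproducible counterpart of an interactive QC viewer: for every
#' requested frequency band and recording condition it renders a
#' topographic map of the per-electrode band power, per-electrode
#' spectrum curves for selected electrodes, and a dispersion-versus-
#' frequency curve per condition. Everything plotted is also written to
#' a machine-readable TSV, so no number exists only in a figure, and
#' the colour scaling never alters the stored values.
#'
#' @param specs named list (by condition tag) of [band_means()] results.
#' @param mont the `eeg_montage` shared by the conditions.
#' @param bands list of `c(lo, hi)` centre-frequency ranges.
#' @param electrodes electrode labels for the spectrum-curve panel.
#' @param out_dir output directory (created if needed).
#' @param scale `"log10"` or `"linear"` colour mapping for the maps.
#' @return Invisibly, a list with the written file paths (`png`,
#'   `html`, `tsv`) and the plotted numbers (`band_values`,
#'   `spectra`, `dispersion` data.frames).
#' @export
comparison_report <- function(specs, mont, bands = list(c(15, 25)),
                              electrodes = c("F3", "F4", "FC3", "FC4",
                                             "C3", "C4"),
                              out_dir, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  if (!length(specs)) stop("need at least one condition")
  conds <- names(specs)
  pref <- c("separate", "outside", "pre_acquisition", "simultaneous")
  conds <- c(intersect(pref, conds), setdiff(conds, pref))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  band_rows <- list(); spec_rows <- list(); disp_rows <- list()
  pngs <- character(0)

  for (bd in bands) {
    vals <- lapply(conds, function(cn)
      band_mean_range(specs[[cn]], bd[1], bd[2]))
    names(vals) <- conds
    for (cn in conds)
      band_rows[[length(band_rows) + 1L]] <-
        data.frame(condition = cn, band_lo = bd[1], band_hi = bd[2],
                   electrode = names(vals[[cn]]),
                   band_mean_uV2 = unname(vals[[cn]]))
    fn <- file.path(out_dir, sprintf("topomap_%g-%g.png", bd[1], bd[2]))
    grDevices::png(fn, width = 320 * length(conds), height = 360)
    graphics::par(mfrow = c(1, length(conds)), mar = c(1, 1, 3, 1))
    for (cn in conds)
      plot(topomap(vals[[cn]], mont, scale = scale),
           main = sprintf("%s %g-%g Hz", cn, bd[1], bd[2]))
    grDevices::dev.off()
    pngs <- c(pngs, fn)
  }

  electrodes <- intersect(electrodes, mont$labels)
  for (cn in conds) {
    sp <- specs[[cn]]
    for (el in electrodes)
      spec_rows[[length(spec_rows) + 1L]] <-
        data.frame(condition = cn, electrode = el,
                   center_freq = sp$band_centers,
                   band_mean_uV2 = unname(sp$band_means[el, ]))
    dc <- dispersion_curve(sp, condition = cn)
    disp_rows[[length(disp_rows) + 1L]] <-
      data.frame(condition = cn, center_freq = dc$band_centers,
                 dispersion_uV2 = unname(dc$dispersion))
  }

  fn <- file.path(out_dir, "spectra.png")
  grDevices::png(fn, width = 720, height = 420)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  sdf <- do.call(rbind, spec_rows)
  graphics::matplot(specs[[conds[1]]]$band_centers,
                    sapply(conds, function(cn)
                      colMeans(specs[[cn]]$band_means[electrodes, , drop = FALSE])),
                    type = "l", lty = 1, log = "y",
                    xlab = "centre frequency (Hz)",
                    ylab = expression(A^2 ~ (mu * V^2)),
                    main = "mean spectrum, selected electrodes")
  graphics::legend("topright", legend = conds, col = seq_along(conds),
                   lty = 1, cex = 0.7)
  ddf <- do.call(rbind, disp_rows)
  graphics::matplot(specs[[conds[1]]]$band_centers,
                    sapply(conds, function(cn)
                      ddf$dispersion_uV2[ddf$condition == cn]),
                    type = "l", lty = 1, log = "y",
                    xlab = "centre frequency (Hz)",
                    ylab = expression(dispersion ~ (mu * V^2)),
                    main = "index of dispersion")
  grDevices::dev.off()
  pngs <- c(pngs, fn)

  bdf <- do.call(rbind, band_rows)
  tsv <- file.path(out_dir, "report_values.tsv")
  all_rows <- rbind(
    data.frame(table = "band", condition = bdf$condition,
               electrode = bdf$electrode, center_freq = NA,
               band_lo = bdf$band_lo, band_hi = bdf$band_hi,
               value = bdf$band_mean_uV2),
    data.frame(table = "spectrum", condition = sdf$condition,
               electrode = sdf$electrode, center_freq = sdf$center_freq,
               band_lo = NA, band_hi = NA, value = sdf$band_mean_uV2),
    data.frame(table = "dispersion", condition = ddf$condition,
               electrode = NA, center_freq = ddf$center_freq,
               band_lo = NA, band_hi = NA, value = ddf$dispersion_uV2))
  all_rows$value <- sprintf("%.17g", all_rows$value)  # bit-exact re-ingest
  utils::write.table(all_rows, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  html <- file.path(out_dir, "report.html")
  writeLines(c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
               "<title>EEG-fMRI quality report</title></head><body>",
               "<h1>EEG-fMRI signal-quality report</h1>",
               sprintf("<p>Conditions: %s</p>", paste(conds, collapse = ", ")),
               sprintf("<h2>%s</h2><img src='%s' width='90%%'>",
                       basename(pngs), basename(pngs)),
               sprintf("<p>All plotted values: <a href='%s'>%s</a></p>",
                       basename(tsv), basename(tsv)),
               "</body></html>"), html)

  invisible(list(png = pngs, html = html, tsv = tsv,
                 band_values = bdf, spectra = sdf, dispersion = ddf))
}
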