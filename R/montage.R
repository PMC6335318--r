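#' Electrode montage
#'
#' A montage holds the ordered 10-5 electrode labels, their unit-sphere
#' positions, the amplifier each channel is wired to, and the symmetric
#' left-right pairing of non-midline electrodes (F3-F4, PO7-PO8, ...).
#' Paired electrodes are required to share an amplifier, matching dual
#' 32-channel amplifier setups where homologous channels are always
#' recorded on the same amplifier.
#'
#' @param labels character vector of unique electrode labels.
#' @param positions numeric matrix (n x 3) of unit-norm positions, rows in
#'   `labels` order. Coordinate convention: x right, y anterior, z up
#'   (vertex at c(0, 0, 1)).
#' @param amplifier integer vector (1 or 2) per label.
#' @param pair_overrides optional data.frame with columns `left`, `right`
#'   overriding the automatic odd/even-digit pairing.
#' @return An object of class `eeg_montage` with elements `labels`,
#'   `positions`, `amplifier`, `midline` (logical per label) and `pairs`
#'   (data.frame `left`, `right`, `amplifier`).
#' @export
montage <- function(labels, positions, amplifier, pair_overrides = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("montage error: duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  positions <- as.matrix(positions)
  if (nrow(positions) != length(labels) || ncol(positions) != 3L)
    stop("montage error: positions must be length(labels) x 3")
  nrm <- sqrt(rowSums(positions^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("montage error: positions must have unit norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  rownames(positions) <- labels
  amplifier <- as.integer(amplifier)
  if (length(amplifier) != length(labels) || !all(amplifier %in% c(1L, 2L)))
    stop("montage error: amplifier must be 1 or 2 per label")
  names(amplifier) <- labels

  parsed <- parse_1005_labels(labels)
  midline <- parsed$midline
  pairs <- derive_pairs(labels, parsed, pair_overrides)
  unpaired <- setdiff(labels[!midline], c(pairs$left, pairs$right))
  if (length(unpaired))
    stop("montage error: unpaired non-midline electrode(s): ",
         paste(unpaired, collapse = ", "))
  amp_l <- amplifier[pairs$left]
  amp_r <- amplifier[pairs$right]
  if (any(amp_l != amp_r))
    stop("montage error: paired electrodes on different amplifiers: ",
         paste(pairs$left[amp_l != amp_r], pairs$right[amp_l != amp_r],
               sep = "-", collapse = ", "))
  pairs$amplifier <- as.integer(amp_l)

  structure(list(labels = labels, positions = positions,
                 amplifier = amplifier, midline = midline, pairs = pairs),
            class = "eeg_montage")
}

# Split 10-5 labels into row prefix and digit/z suffix.
parse_1005_labels <- function(labels) {
  m <- regmatches(labels, regexec("^([A-Za-z]+?)(z|[0-9]+)$", labels))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("montage error: label(s) not in 10-5 form: ",
         paste(labels[bad], collapse = ", "))
  row <- vapply(m, `[`, "", 2L)
  suf <- vapply(m, `[`, "", 3L)
  list(row = row, suffix = suf, midline = suf == "z",
       digit = suppressWarnings(as.integer(suf)))
}

# Odd digits are left hemisphere and pair with digit + 1 on the same row.
derive_pairs <- function(labels, parsed, pair_overrides = NULL) {
  left <- character(0); right <- character(0)
  if (!is.null(pair_overrides)) {
    left <- as.character(pair_overrides$left)
    right <- as.character(pair_overrides$right)
  }
  taken <- c(left, right)
  for (i in seq_along(labels)) {
    if (parsed$midline[i] || labels[i] %in% taken) next
    d <- parsed$digit[i]
    if (is.na(d)) next
    if (d %% 2L == 1L) {
      partner <- paste0(parsed$row[i], d + 1L)
      if (partner %in% labels && !(partner %in% taken)) {
        left <- c(left, labels[i]); right <- c(right, partner)
        taken <- c(taken, labels[i], partner)
      }
    }
  }
  ord <- order(left)
  data.frame(left = left[ord], right = right[ord],
             stringsAsFactors = FALSE)
}

#' Load a montage from a TSV file
#'
#' Expects tab-separated columns `label`, `x`, `y`, `z`, `amplifier`.
#' Labels are sorted alphabetically; left-right pairs are derived from the
#' odd/even digit convention of the 10-5 system (F3 pairs F4, P7 pairs P8),
#' with optional explicit overrides.
#'
#' @param path path to the TSV file.
#' @param pair_overrides see [montage()].
#' @return An `eeg_montage`.
#' @export
load_montage <- function(path, pair_overrides = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "x", "y", "z", "amplifier")
  if (!all(need %in% names(tab)))
    stop("montage error: TSV must have columns ",
         paste(need, collapse = ", "))
  tab <- tab[order(tab$label), , drop = FALSE]
  montage(tab$label, as.matrix(tab[, c("x", "y", "z")]), tab$amplifier,
          pair_overrides = pair_overrides)
}

#' The packaged 60-channel 10-5 montage
#'
#' Sixty alphabetically sorted electrodes common to typical 64-channel MR
#' caps (26 symmetric non-midline pairs plus 8 midline electrodes), with
#' the dual-amplifier channel assignment of a 2 x 32-channel MR amplifier
#' stack. Positions are an idealized symmetric spherical layout.
#'
#' @return An `eeg_montage` with 60 labels.
#' @export
standard_montage <- function() {
  load_montage(system.file("extdata", "montage_10_5_60ch.tsv",
                           package = "eegfmriqc", mustWork = TRUE))
}

#' Restrict a montage to a subset of electrodes
#'
#' Keeps only complete left-right pairs and midline electrodes among
#' `keep`.
#'
#' @param mont an `eeg_montage`.
#' @param keep labels to retain.
#' @return An `eeg_montage`.
#' @export
montage_subset <- function(mont, keep) {
  keep <- intersect(mont$labels, keep)
  p <- mont$pairs
  ok_pair <- p$left %in% keep & p$right %in% keep
  keep2 <- c(mont$labels[mont$midline][mont$labels[mont$midline] %in% keep],
             p$left[ok_pair], p$right[ok_pair])
  keep2 <- mont$labels[mont$labels %in% keep2]
  montage(keep2, mont$positions[keep2, , drop = FALSE],
          mont$amplifier[keep2])
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$labels), " electrodes: ",
      nrow(x$pairs), " left-right pairs, ", sum(x$midline),
      " midline\n", sep = "")
  invisible(x)
}

# Idealized 10-5 positions: a row/digit grid in degrees mapped through the
# inverse azimuthal-equidistant projection, so the projected 2D layout is
# recovered exactly and the layout is exactly left-right symmetric.
ideal_1005_position <- function(labels) {
  row_ap <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0, CP = -18,
              P = -36, PO = -54, O = -72, T = 0, FT = 18, TP = -18)
  parsed <- parse_1005_labels(labels)
  lat_mag <- c(18, 18, 36, 36, 54, 54, 72, 72)
  pos <- matrix(0, length(labels), 3, dimnames = list(labels, c("x", "y", "z")))
  for (i in seq_along(labels)) {
    row <- parsed$row[i]
    if (!row %in% names(row_ap))
      stop("no idealized position for row ", row)
    ap <- row_ap[[row]]
    if (parsed$midline[i]) lat <- 0
    else {
      d <- parsed$digit[i]
      lat <- lat_mag[d] * if (d %% 2L == 1L) -1 else 1
      if (row %in% c("T", "FT", "TP")) lat <- sign(lat) * 72
    }
    th <- sqrt(lat^2 + ap^2) * pi / 180
    if (th == 0) pos[i, ] <- c(0, 0, 1)
    else {
      u <- c(lat, ap) / sqrt(lat^2 + ap^2)
      pos[i, ] <- c(sin(th) * u[1], sin(th) * u[2], cos(th))
    }
  }
  pos
}
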