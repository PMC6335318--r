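#' Read an EEG recording
#'
#' Dispatches on format: BrainVision (`.vhdr`/`.vmrk`/`.eeg`) or EDF.
#' Amplitudes are converted to microvolts; marker descriptions can be
#' mapped to canonical event labels (`tr_onset`, `stimulus`, `r_peak`)
#' through `marker_map`, since vendor marker strings are site-specific.
#'
#' @param path path to the header file (`.vhdr` for BrainVision, `.edf`).
#' @param format `"brainvision"` or `"edf"`.
#' @param marker_map optional named character vector or list mapping marker
#'   descriptions to event labels, e.g. `c("R128" = "tr_onset")`; see also
#'   [read_config()].
#' @return An [eeg_recording()].
#' @export
read_eeg <- function(path, format = c("brainvision", "edf"),
                     marker_map = NULL) {
  format <- match.arg(format)
  rec <- switch(format,
                brainvision = read_brainvision(path),
                edf = read_edf(path))
  if (!is.null(marker_map) && nrow(rec$events)) {
    mm <- unlist(marker_map)
    hit <- rec$events$label %in% names(mm)
    rec$events$label[hit] <- unname(mm[rec$events$label[hit]])
  }
  rec
}

#' Write an EEG recording
#'
#' BrainVision files are written as multiplexed binary with an INI-style
#' header; `binary_format = "float32"` round-trips exactly, `"int16"`
#' quantizes at `resolution` microvolts per bit. EDF always quantizes to
#' 16 bit; its events are stored in a `<path>.events.tsv` sidecar
#' (columns `sample`, `label`) because classic EDF has no marker track.
#'
#' @param rec an [eeg_recording()].
#' @param path output path (`.vhdr` or `.edf`).
#' @param format `"brainvision"` or `"edf"`.
#' @param binary_format BrainVision sample encoding.
#' @param resolution microvolts per bit for `"int16"`.
#' @return Invisibly, `path`.
#' @export
write_eeg <- function(rec, path, format = c("brainvision", "edf"),
                      binary_format = c("float32", "int16"),
                      resolution = 0.1) {
  format <- match.arg(format)
  binary_format <- match.arg(binary_format)
  switch(format,
         brainvision = write_brainvision(rec, path, binary_format, resolution),
         edf = write_edf(rec, path))
  invisible(path)
}

# --- BrainVision ------------------------------------------------------------

parse_ini <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list(); section <- ""
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln, fixed = TRUE), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

ini_get <- function(ini, section, key) {
  v <- ini[[section]][[key]]
  if (is.null(v))
    stop("format error: BrainVision header missing [", section, "] ", key)
  v
}

read_brainvision <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  ini <- parse_ini(readLines(path, warn = FALSE))
  dir <- dirname(path)
  n_ch <- as.integer(ini_get(ini, "Common Infos", "NumberOfChannels"))
  samp_int_us <- as.numeric(ini_get(ini, "Common Infos", "SamplingInterval"))
  fs <- 1e6 / samp_int_us
  orient <- ini_get(ini, "Common Infos", "DataOrientation")
  if (toupper(orient) != "MULTIPLEXED")
    stop("format error: unsupported DataOrientation: ", orient)
  binfmt <- ini_get(ini, "Binary Infos", "BinaryFormat")
  data_file <- file.path(dir, ini_get(ini, "Common Infos", "DataFile"))
  marker_file <- ini[["Common Infos"]][["MarkerFile"]]

  labels <- character(n_ch); res <- numeric(n_ch); unit <- character(n_ch)
  for (i in seq_len(n_ch)) {
    entry <- ini_get(ini, "Channel Infos", paste0("Ch", i))
    parts <- strsplit(entry, ",", fixed = TRUE)[[1]]
    labels[i] <- parts[1]
    res[i] <- if (length(parts) >= 3 && nzchar(parts[3])) as.numeric(parts[3]) else 1
    unit[i] <- if (length(parts) >= 4) parts[4] else "µV"
  }
  known_uv <- c("µV", "uV", "μV", "microvolt", "microvolts")
  if (!all(unit %in% known_uv))
    stop("unit error: unknown channel unit(s): ",
         paste(unique(setdiff(unit, known_uv)), collapse = ", "))

  sz <- file.size(data_file)
  if (toupper(binfmt) == "IEEE_FLOAT_32") {
    n_samp <- sz / (4 * n_ch)
    raw <- readBin(data_file, "numeric", n = n_ch * n_samp, size = 4,
                   endian = "little")
  } else if (toupper(binfmt) == "INT_16") {
    n_samp <- sz / (2 * n_ch)
    raw <- readBin(data_file, "integer", n = n_ch * n_samp, size = 2,
                   signed = TRUE, endian = "little")
  } else stop("format error: unsupported BinaryFormat: ", binfmt)
  if (n_samp != round(n_samp))
    stop("format error: data file size not a multiple of the frame size")
  data <- matrix(raw, nrow = n_ch) * res
  rownames(data) <- labels

  events <- data.frame(latency = integer(0), label = character(0),
                       stringsAsFactors = FALSE)
  if (!is.null(marker_file) && file.exists(file.path(dir, marker_file))) {
    mrk <- parse_ini(readLines(file.path(dir, marker_file), warn = FALSE))
    mk <- mrk[["Marker Infos"]]
    if (!is.null(mk)) {
      lat <- integer(0); lab <- character(0)
      for (key in names(mk)) {
        parts <- strsplit(mk[[key]], ",", fixed = TRUE)[[1]]
        # Type,Description,Position(1-based),Size,Channel
        lab <- c(lab, parts[2])
        lat <- c(lat, as.integer(parts[3]) - 1L)  # to 0-based
      }
      ord <- order(lat)
      events <- data.frame(latency = lat[ord], label = lab[ord],
                           stringsAsFactors = FALSE)
    }
  }
  eeg_recording(data, fs, events = events)
}

write_brainvision <- function(rec, path, binary_format, resolution) {
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  stem <- sub("\\.vhdr$", "", basename(path))
  dir <- dirname(path)
  data_name <- paste0(stem, ".eeg"); mrk_name <- paste0(stem, ".vmrk")
  n_ch <- nrow(rec$data)
  labels <- rownames(rec$data)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(n_ch))
  binfmt <- if (binary_format == "float32") "IEEE_FLOAT_32" else "INT_16"
  res <- if (binary_format == "float32") rep(1, n_ch) else rep(resolution, n_ch)

  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", data_name),
           paste0("MarkerFile=", mrk_name),
           "DataFormat=BINARY",
           "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", n_ch),
           paste0("SamplingInterval=", format(1e6 / rec$fs, digits = 15)),
           "[Binary Infos]",
           paste0("BinaryFormat=", binfmt),
           "[Channel Infos]",
           sprintf("Ch%d=%s,,%s,µV", seq_len(n_ch), labels,
                   format(res, digits = 15)))
  con <- file(path, "wb"); writeLines(hdr, con, sep = "\r\n"); close(con)

  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "[Common Infos]",
           "Codepage=UTF-8",
           paste0("DataFile=", data_name),
           "[Marker Infos]")
  if (nrow(rec$events))
    mrk <- c(mrk, sprintf("Mk%d=Stimulus,%s,%d,1,0",
                          seq_len(nrow(rec$events)), rec$events$label,
                          rec$events$latency + 1L))
  con <- file(file.path(dir, mrk_name), "wb")
  writeLines(mrk, con, sep = "\r\n"); close(con)

  x <- as.vector(rec$data)  # multiplexed: channel-fastest
  con <- file(file.path(dir, data_name), "wb")
  if (binary_format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    q <- as.integer(round(x / resolution))
    if (any(abs(q) > 32767L)) {
      close(con)
      stop("I/O error: int16 overflow; increase resolution (uV/bit)")
    }
    writeBin(q, con, size = 2, endian = "little")
  }
  close(con)
  invisible(path)
}
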