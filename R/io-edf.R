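# Minimal classic-EDF reader/writer: 16-bit samples with per-signal
# physical/digital calibration, one data record spanning a configurable
# duration. Events travel in a "<path>.events.tsv" sidecar (sample, label)
# because classic EDF has no annotation track.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  version <- fld(hdr, 1, 8)
  if (version != "0") stop("format error: EDF version field must be '0', got '",
                           version, "'")
  n_rec <- as.integer(fld(hdr, 237, 8))
  rec_dur <- as.numeric(fld(hdr, 245, 8))
  n_sig <- as.integer(fld(hdr, 253, 4))
  if (is.na(n_sig) || n_sig < 1L)
    stop("format error: bad number-of-signals field")
  sig_hdr <- rawToChar(readBin(con, "raw", 256L * n_sig))
  grab <- function(off, len) {
    vapply(seq_len(n_sig), function(i)
      trimws(substr(sig_hdr, off + (i - 1L) * len + 1L, off + i * len)), "")
  }
  labels <- grab(0L, 16L)
  dims <- grab(n_sig * (16L + 80L), 8L)
  phys_min <- as.numeric(grab(n_sig * (16L + 80L + 8L), 8L))
  phys_max <- as.numeric(grab(n_sig * (16L + 80L + 16L), 8L))
  dig_min <- as.numeric(grab(n_sig * (16L + 80L + 24L), 8L))
  dig_max <- as.numeric(grab(n_sig * (16L + 80L + 32L), 8L))
  n_samp_rec <- as.integer(grab(n_sig * (16L + 80L + 40L + 80L), 8L))
  known_uv <- c("uV", "µV", "μV")
  if (!all(dims %in% known_uv))
    stop("unit error: unknown EDF physical dimension(s): ",
         paste(unique(setdiff(dims, known_uv)), collapse = ", "))
  if (length(unique(n_samp_rec)) != 1L)
    stop("format error: heterogeneous samples-per-record not supported")
  fs <- n_samp_rec[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)

  data <- matrix(0, n_sig, n_samp_rec[1] * n_rec)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(n_sig)) {
      d <- readBin(con, "integer", n_samp_rec[1], size = 2, signed = TRUE,
                   endian = "little")
      idx <- (r - 1L) * n_samp_rec[1] + seq_len(n_samp_rec[1])
      data[s, idx] <- phys_min[s] + (d - dig_min[s]) * gain[s]
    }
  }
  rownames(data) <- labels

  events <- NULL
  sidecar <- paste0(path, ".events.tsv")
  if (file.exists(sidecar)) {
    tab <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    events <- data.frame(latency = as.integer(tab$sample),
                         label = as.character(tab$label),
                         stringsAsFactors = FALSE)
  }
  eeg_recording(data, fs, events = events)
}

write_edf <- function(rec, path) {
  n_sig <- nrow(rec$data); n_samp <- ncol(rec$data)
  labels <- rownames(rec$data)
  if (is.null(labels)) labels <- paste0("Ch", seq_len(n_sig))
  # one data record holding the whole signal
  rec_dur <- n_samp / rec$fs
  amax <- max(1, ceiling(max(abs(rec$data))))
  phys_min <- -amax; phys_max <- amax
  dig_min <- -32767; dig_max <- 32767

  con <- file(path, "wb"); on.exit(close(con))
  wf <- function(x, width) writeChar(pad_field(x, width), con, eos = NULL)
  wf("0", 8); wf("X X X X", 80); wf("Startdate X", 80)
  wf("01.01.00", 8); wf("00.00.00", 8)
  wf(256L + 256L * n_sig, 8); wf("", 44)
  wf(1L, 8)                                   # n records
  wf(format(rec_dur, digits = 8), 8)
  wf(n_sig, 4)
  for (l in labels) wf(l, 16)
  for (i in seq_len(n_sig)) wf("", 80)        # transducer
  for (i in seq_len(n_sig)) wf("uV", 8)
  for (i in seq_len(n_sig)) wf(format(phys_min, digits = 7), 8)
  for (i in seq_len(n_sig)) wf(format(phys_max, digits = 7), 8)
  for (i in seq_len(n_sig)) wf(dig_min, 8)
  for (i in seq_len(n_sig)) wf(dig_max, 8)
  for (i in seq_len(n_sig)) wf("", 80)        # prefiltering
  for (i in seq_len(n_sig)) wf(n_samp, 8)
  for (i in seq_len(n_sig)) wf("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (s in seq_len(n_sig)) {
    d <- as.integer(pmin(pmax(round((rec$data[s, ] - phys_min) / gain + dig_min),
                              dig_min), dig_max))
    writeBin(d, con, size = 2, endian = "little")
  }
  if (nrow(rec$events)) {
    utils::write.table(
      data.frame(sample = rec$events$latency, label = rec$events$label),
      paste0(path, ".events.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
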