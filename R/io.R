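pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a segment as a 16-bit EDF file
#'
#' Minimal EDF (European Data Format) writer: a standard 256-byte header
#' plus one 256-byte header block per signal, followed by data records
#' of little-endian 16-bit integers. All channels share the segment's
#' sampling rate; physical calibration is chosen per channel from the
#' data range, so the quantisation step is `(max - min) / 65535`. The
#' segment is truncated to a whole number of `record_duration`-second
#' records.
#'
#' @param segment A [ts_segment()].
#' @param path Output path.
#' @param record_duration Data-record length, s (default 1; must give an
#'   integer number of samples).
#' @return `path`, invisibly.
#' @export
write_edf <- function(segment, path, record_duration = 1) {
  x <- segment$samples
  fs <- segment$fs
  spr <- fs * record_duration
  if (abs(spr - round(spr)) > 1e-9)
    stop("record_duration * fs must be an integer number of samples")
  spr <- as.integer(round(spr))
  nrec <- ncol(x) %/% spr
  if (nrec < 1L) stop("segment shorter than one data record")
  x <- x[, seq_len(nrec * spr), drop = FALSE]
  ns <- nrow(x)
  pmin_ <- apply(x, 1, min); pmax_ <- apply(x, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(pad_ascii(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(if (is.na(segment$subject)) "X" else segment$subject, 80)
  wr("iceegnorm synthetic segment", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(nrec, 8)
  wr(format(record_duration), 8)
  wr(ns, 4)
  for (s in segment$labels) wr(s, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in pmin_) wr(formatC(v, digits = 5, format = "g"), 8)
  for (v in pmax_) wr(formatC(v, digits = 5, format = "g"), 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(spr, 8)
  for (i in seq_len(ns)) wr("", 32)
  # re-read the written physical limits so scaling is exactly invertible
  pmin_w <- as.numeric(pad_ascii(formatC(pmin_, digits = 5, format = "g"), 8))
  pmax_w <- as.numeric(pad_ascii(formatC(pmax_, digits = 5, format = "g"), 8))
  gain <- (pmax_w - pmin_w) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(ns)) {
      d <- round((x[ch, idx] - pmin_w[ch]) / gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file into a segment
#'
#' Counterpart of [write_edf()]: parses the EDF header, reads the data
#' records and applies the per-channel physical calibration. Requires
#' all signals to share one sampling rate (the pipeline's referential
#' montage assumption); EDF+ annotation channels are not supported.
#'
#' @param path Path to an EDF file.
#' @return A [ts_segment()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8)                       # version
  subject <- rd(80)
  rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)           # transducer
  for (i in seq_len(ns)) rd(8)            # physical dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)           # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF signals with differing sampling rates are not supported")
  fs <- spr[1] / recdur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- matrix(0, ns, nrec * spr[1])
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    for (ch in seq_len(ns)) {
      d <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                   signed = TRUE)
      x[ch, idx] <- pmin_[ch] + (d - dmin[ch]) * gain[ch]
    }
  }
  ts_segment(x, fs, labels,
             subject = if (identical(subject, "X")) NA_character_ else subject)
}

#' Write a segment as a plain TSV interchange pair
#'
#' Writes `<prefix>_channels.tsv` (channel metadata: label, sampling
#' rate, subject) and `<prefix>_data.tsv` (samples, one column per
#' channel, one row per time point). Lossless up to text precision;
#' readable by any table tool.
#'
#' @param segment A [ts_segment()].
#' @param prefix Path prefix for the two files.
#' @return The two paths, invisibly.
#' @export
write_segment_tsv <- function(segment, prefix) {
  meta <- data.frame(label = segment$labels, fs = segment$fs,
                     subject = segment$subject)
  pm <- paste0(prefix, "_channels.tsv")
  pd <- paste0(prefix, "_data.tsv")
  utils::write.table(meta, pm, sep = "\t", quote = FALSE, row.names = FALSE)
  dat <- as.data.frame(t(segment$samples))
  names(dat) <- segment$labels
  utils::write.table(dat, pd, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(channels = pm, data = pd))
}

#' Read a segment written by [write_segment_tsv()]
#' @param prefix Path prefix used when writing.
#' @return A [ts_segment()].
#' @export
read_segment_tsv <- function(prefix) {
  meta <- utils::read.table(paste0(prefix, "_channels.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  dat <- utils::read.table(paste0(prefix, "_data.tsv"), header = TRUE,
                           sep = "\t")
  ts_segment(t(as.matrix(dat)), meta$fs[1], meta$label,
             subject = as.character(meta$subject[1]))
}
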