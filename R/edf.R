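# Minimal European Data Format (EDF, 16-bit) reader/writer. Covers exactly the
# subset this package emits: continuous multichannel records, one physical
# dimension (uV), equal sampling rate across signals, 1 s data records.
# Session metadata is round-tripped through the 80-byte recording-id field.

padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with 1 s data records, physical dimension uV and channel labels
#' taken from the montage. Subject/group/lag/condition/block metadata are
#' encoded in the recording-identification header field and restored by
#' [readEDF()]. Samples beyond the last whole second are dropped (EDF records
#' are fixed-length) with a warning.
#'
#' @param rec an [EEGRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(rec, path) {
  dat <- eegData(rec)
  fs <- samplingRate(rec)
  stopifnot(fs == round(fs))
  ns <- nrow(dat)
  nRec <- floor(ncol(dat) / fs)
  if (nRec * fs < ncol(dat)) {
    warning("dropping ", ncol(dat) - nRec * fs, " samples beyond the last whole second")
  }
  dat <- dat[, seq_len(nRec * fs), drop = FALSE]
  physMin <- floor(min(dat, -1))
  physMax <- ceiling(max(dat, 1))
  digMin <- -32768
  digMax <- 32767
  scale <- (digMax - digMin) / (physMax - physMin)
  dig <- round((dat - physMin) * scale + digMin)
  dig[dig < digMin] <- digMin
  dig[dig > digMax] <- digMax
  recId <- sprintf("subject=%s group=%s lag=%s cond=%s block=%d",
                   rec@subject, rec@group, rec@lag, rec@condition, rec@block)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    padField("0", 8), padField(rec@subject, 80), padField(recId, 80),
    padField("01.01.24", 8), padField("00.00.00", 8),
    padField(256 + ns * 256, 8), padField("", 44),
    padField(nRec, 8), padField(1, 8), padField(ns, 4)
  ), con, eos = NULL)
  writeChar(paste0(
    paste(padField(rec@montage$label, 16), collapse = ""),
    paste(rep(padField("AgAgCl electrode", 80), ns), collapse = ""),
    paste(rep(padField("uV", 8), ns), collapse = ""),
    paste(rep(padField(physMin, 8), ns), collapse = ""),
    paste(rep(padField(physMax, 8), ns), collapse = ""),
    paste(rep(padField(digMin, 8), ns), collapse = ""),
    paste(rep(padField(digMax, 8), ns), collapse = ""),
    paste(rep(padField("", 80), ns), collapse = ""),
    paste(rep(padField(fs, 8), ns), collapse = ""),
    paste(rep(padField("", 32), ns), collapse = "")
  ), con, eos = NULL)
  for (r in seq_len(nRec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, idx])), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [writeEDF()]
#'
#' @param path EDF file path.
#' @param montage montage to attach; channel labels must match the file's.
#' @return An [EEGRecording-class].
#' @export
readEDF <- function(path, montage = montage1010()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                              # version
  subject <- trimws(rd(80))
  recId <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  rd(80 * ns); rd(8 * ns)
  physMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  stopifnot(length(unique(spr)) == 1)
  fs <- spr[1] / recDur
  dat <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2, endian = "little")
    dat[, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
      t(matrix(raw, spr[1], ns))
  }
  for (ch in seq_len(ns)) {
    sc <- (physMax[ch] - physMin[ch]) / (digMax[ch] - digMin[ch])
    dat[ch, ] <- (dat[ch, ] - digMin[ch]) * sc + physMin[ch]
  }
  meta <- list(group = NA_character_, lag = "pre", cond = "eo_sit", block = 1L)
  for (kv in strsplit(recId, " ")[[1]]) {
    p <- strsplit(kv, "=")[[1]]
    if (length(p) == 2) meta[[p[1]]] <- p[2]
  }
  if (identical(meta$group, "NA")) meta$group <- NA_character_
  stopifnot(identical(labels, montage$label))
  EEGRecording(dat, fs = fs, subject = subject,
               group = meta$group, lag = meta$lag, condition = meta$cond,
               block = as.integer(meta$block), montage = montage)
}
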