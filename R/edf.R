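# Minimal EDF (European Data Format) I/O: fixed-width ASCII header blocks and
# 16-bit little-endian sample records. Covers the subset needed to persist
# synthetic cohorts: identical sampling rate on all signals, 1-s data records.

edf_pad <- function(x, width) {
  x <- as.character(x)
  x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Signals are scaled per channel to the 16-bit digital range, so values are
#' preserved to within one quantization step of the channel's physical range.
#' The recording is split into 1-second data records; a trailing partial
#' second is dropped.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("write_edf requires an integer sampling rate")
  fs <- as.integer(round(fs))
  nrec <- n_samples(rec) %/% fs
  if (nrec < 1L) stop("recording shorter than one data record (1 s)")
  nch <- n_channels(rec)
  dat <- rec$data[, seq_len(nrec * fs), drop = FALSE]

  pmin <- apply(dat, 1L, min); pmax <- apply(dat, 1L, max)
  flat <- pmax - pmin < .Machine$double.eps
  pmin[flat] <- pmin[flat] - 1; pmax[flat] <- pmax[flat] + 1
  dmin <- -32768; dmax <- 32767
  gain <- (dmax - dmin) / (pmax - pmin)
  dig <- round(sweep(sweep(dat, 1L, pmin), 1L, gain, `*`)) + dmin
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  label <- sprintf("%s %s %s", rec$subject_id, rec$group, rec$state)
  writeChar(paste0(
    edf_pad("0", 8), edf_pad(label, 80), edf_pad("synthetic EEG", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(nrec, 8), edf_pad(1, 8), edf_pad(nch, 4)),
    con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec$channel_labels, 16)                       # label
  field(rep("AgAgCl electrode", nch), 80)             # transducer
  field(rep("uV", nch), 8)                            # physical dimension
  field(formatC(pmin, digits = 6, format = "g"), 8)   # physical min
  field(formatC(pmax, digits = 6, format = "g"), 8)   # physical max
  field(rep(dmin, nch), 8)                            # digital min
  field(rep(dmax, nch), 8)                            # digital max
  field(rep("", nch), 80)                             # prefiltering
  field(rep(fs, nch), 8)                              # samples per record
  field(rep("", nch), 32)                             # reserved

  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An [eeg_recording()]; subject/group/state metadata are recovered
#'   from the patient identification field when present.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  patient <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  nrec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  rdv <- function(width) vapply(seq_len(nch), function(i) rd(width), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  ns <- as.integer(rdv(8)); rdv(32)
  if (length(unique(ns)) != 1L) stop("mixed per-signal sampling rates unsupported")
  fs <- ns[1L] / rec_dur

  dat <- matrix(0, nch, nrec * ns[1L])
  for (r in seq_len(nrec)) {
    block <- readBin(con, "integer", n = nch * ns[1L], size = 2L,
                     signed = TRUE, endian = "little")
    dat[, ((r - 1L) * ns[1L] + 1L):(r * ns[1L])] <-
      t(matrix(block, ns[1L], nch))
  }
  gain <- (pmax - pmin) / (dmax - dmin)
  dat <- sweep(sweep(dat, 1L, dmin), 1L, gain, `*`)
  dat <- sweep(dat, 1L, pmin, `+`)

  meta <- strsplit(patient, " ", fixed = TRUE)[[1L]]
  meta <- c(meta, rep(NA_character_, 3L))[1:3]
  eeg_recording(dat, fs, labels, subject_id = meta[1L], group = meta[2L],
                state = meta[3L])
}
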