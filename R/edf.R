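# European Data Format (EDF): 256-byte fixed header, 256 bytes of signal
# header per channel, then data records of 16-bit little-endian integers
# with per-channel linear physical scaling. Written with 1-s records.

.edfField <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width)
    stop("EDF header field too long (> ", width, " chars): '", s, "'")
  formatC(s, width = width, flag = "-")
}

.edfNum <- function(x, width = 8) {
  for (d in 6:1) {
    s <- formatC(signif(x, d), format = "g", width = 1, digits = d)
    if (nchar(s) <= width) return(.edfField(s, width))
  }
  stop("cannot represent ", x, " in an 8-character EDF field")
}

#' Write a recording as a 16-bit EDF file
#'
#' Samples are stored in physical units of µV with a symmetric per-channel
#' physical range, so the worst-case round-trip error is one quantization
#' step (`range / 65535`). The recording must span a whole number of
#' 1-second data records.
#'
#' @param recording an [EEGRecording-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEDF <- function(recording, path) {
  stopifnot(is(recording, "EEGRecording"))
  x <- recording@samples
  labels <- recording@channelLabels
  if (any(nchar(labels) > 16L))
    stop("EDF labels are limited to 16 characters: ",
         paste(labels[nchar(labels) > 16L], collapse = ", "))
  nr <- round(recording@fs)
  if (abs(nr - recording@fs) > 1e-9)
    stop("writeEDF requires an integer sampling rate for 1-s records")
  if (ncol(x) %% nr != 0L)
    stop("recording length must be a whole number of 1-s records")
  nRecords <- ncol(x) %/% nr
  ns <- nrow(x)

  physMax <- apply(abs(x), 1L, max)
  physMax[physMax == 0] <- 1
  physMax <- signif(physMax * (1 + 1e-9), 6)
  # re-parse the header representation so the scaling used for writing is
  # exactly the one a reader will recover
  physMax <- as.numeric(vapply(physMax, .edfNum, ""))
  # same affine map the reader inverts: dig in [-32768, 32767] over
  # [-physMax, physMax], so round-trip error <= one quantization step
  scale <- 2 * physMax / 65535
  digital <- round(sweep(sweep(x, 1L, physMax, "+"), 1L, scale, "/")) - 32768
  digital[digital > 32767] <- 32767
  digital[digital < -32768] <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edfField("0", 8),
    .edfField(recording@subjectId, 80),
    .edfField("qeegtools", 80),
    .edfField("01.01.00", 8), .edfField("00.00.00", 8),
    .edfField(256 * (1 + ns), 8),
    .edfField("", 44),
    .edfField(nRecords, 8),
    .edfField(1, 8),
    .edfField(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sigHdr <- paste0(
    paste(vapply(labels, .edfField, "", width = 16), collapse = ""),
    paste(rep(.edfField("", 80), ns), collapse = ""),
    paste(rep(.edfField("uV", 8), ns), collapse = ""),
    paste(vapply(-physMax, .edfNum, ""), collapse = ""),
    paste(vapply(physMax, .edfNum, ""), collapse = ""),
    paste(rep(.edfField(-32768, 8), ns), collapse = ""),
    paste(rep(.edfField(32767, 8), ns), collapse = ""),
    paste(rep(.edfField("", 80), ns), collapse = ""),
    paste(rep(.edfField(nr, 8), ns), collapse = ""),
    paste(rep(.edfField("", 32), ns), collapse = ""))
  writeChar(sigHdr, con, eos = NULL)
  for (r in seq_len(nRecords)) {
    cols <- ((r - 1L) * nr + 1L):(r * nr)
    block <- as.integer(t(digital[, cols, drop = FALSE]))
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.readField <- function(con, width, what, offset) {
  s <- readChar(con, width, useBytes = TRUE)
  if (nchar(s, type = "bytes") < width)
    stop("malformed EDF: truncated ", what, " at byte offset ", offset)
  trimws(s)
}

#' Read an EDF file into an EEG recording
#'
#' Supports the common case of all channels sharing one sampling rate.
#' Parse failures report the byte offset of the offending field.
#'
#' @param path EDF file
#' @return an [EEGRecording-class] with samples in physical units
#' @export
readEDF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- .readField(con, 8, "version", 0)
  if (version != "0")
    stop("malformed EDF: bad version field at byte offset 0 (got '",
         version, "')")
  subjectId <- .readField(con, 80, "patient id", 8)
  invisible(.readField(con, 80, "recording id", 88))
  invisible(.readField(con, 8, "start date", 168))
  invisible(.readField(con, 8, "start time", 176))
  invisible(.readField(con, 8, "header bytes", 184))
  invisible(.readField(con, 44, "reserved", 192))
  nRecords <- as.integer(.readField(con, 8, "record count", 236))
  recDur <- as.numeric(.readField(con, 8, "record duration", 244))
  ns <- as.integer(.readField(con, 4, "signal count", 252))
  if (is.na(ns) || ns < 1L)
    stop("malformed EDF: bad signal count at byte offset 252")

  rd <- function(width, what, base)
    vapply(seq_len(ns), function(k)
      .readField(con, width, what, base + (k - 1L) * width), "")
  labels <- rd(16, "label", 256)
  if (anyDuplicated(labels))
    stop("duplicate channel labels in EDF: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  invisible(rd(80, "transducer", 256 + ns * 16))
  units <- rd(8, "physical dimension", 256 + ns * 96)
  physMin <- as.numeric(rd(8, "physical minimum", 256 + ns * 104))
  physMax <- as.numeric(rd(8, "physical maximum", 256 + ns * 112))
  digMin <- as.numeric(rd(8, "digital minimum", 256 + ns * 120))
  digMax <- as.numeric(rd(8, "digital maximum", 256 + ns * 128))
  invisible(rd(80, "prefiltering", 256 + ns * 136))
  nSamp <- as.integer(rd(8, "samples per record", 256 + ns * 216))
  invisible(rd(32, "reserved", 256 + ns * 224))
  if (length(unique(nSamp)) != 1L)
    stop("channels with different sampling rates are not supported")
  if (length(unique(units)) != 1L)
    stop("unit mismatch across channels: ",
         paste(unique(units), collapse = ", "))
  nr <- nSamp[1]
  dataOffset <- 256 * (1 + ns)
  raw <- readBin(con, "integer", n = nRecords * ns * nr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nRecords * ns * nr)
    stop("malformed EDF: data truncated at byte offset ",
         dataOffset + 2 * length(raw))
  x <- matrix(0, ns, nRecords * nr)
  for (r in seq_len(nRecords)) {
    block <- matrix(raw[((r - 1L) * ns * nr + 1L):(r * ns * nr)],
                    nrow = nr, ncol = ns)
    x[, ((r - 1L) * nr + 1L):(r * nr)] <- t(block)
  }
  scale <- (physMax - physMin) / (digMax - digMin)
  x <- x * scale + (physMin - digMin * scale)
  eegRecording(x, fs = nr / recDur, channelLabels = labels,
               subjectId = if (nzchar(subjectId)) subjectId else "subject")
}
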