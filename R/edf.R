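# Minimal European Data Format (EDF) 16-bit I/O.
# Layout: 256-byte fixed header, then ns signal headers stored field-major
# (all labels, then all transducer fields, ...), then data records of
# little-endian int16 samples, one block per signal per record.

edfPad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width, flag = "-")
}

# numeric into an 8-char ASCII field; EDF allows plain or scientific notation
edfNum8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = -1)
    if (nchar(s) <= 8L) return(edfPad(s, 8L))
  }
  stop("cannot format ", x, " into an 8-character EDF field")
}

#' Write a recording to an EDF file
#'
#' Writes standard 16-bit EDF. Each channel is scaled into the full digital
#' range from its own physical extrema, so the round-trip error is bounded by
#' the channel range divided by 65535. Record duration is 1 s when the sample
#' count divides evenly into whole seconds at an integer sampling rate;
#' otherwise the whole signal is stored as a single data record.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @seealso \code{\link{readRecording}}
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  x <- rec@data
  if (any(!is.finite(x)))
    stop("cannot write non-finite samples to EDF")
  nch <- nrow(x)
  n <- ncol(x)
  fs <- rec@fs
  if (abs(fs - round(fs)) < 1e-9 && n %% round(fs) == 0L && n > round(fs)) {
    spr <- as.integer(round(fs))
    nRecords <- n %/% spr
    recDur <- 1
  } else {
    spr <- n
    nRecords <- 1L
    recDur <- n / fs
  }
  physMin <- apply(x, 1L, min)
  physMax <- apply(x, 1L, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMax[flat] + 1
  # quantize against the 8-character header representation the reader will
  # parse, so the round-trip error stays within half a digital step
  physMin <- as.numeric(trimws(vapply(physMin, edfNum8, "")))
  physMax <- as.numeric(trimws(vapply(physMax, edfNum8, "")))
  low <- physMin > apply(x, 1L, min)
  physMin[low] <- physMin[low] - abs(physMin[low]) * 1e-6 - 1e-6
  high <- physMax < apply(x, 1L, max)
  physMax[high] <- physMax[high] + abs(physMax[high]) * 1e-6 + 1e-6
  physMin <- as.numeric(trimws(vapply(physMin, edfNum8, "")))
  physMax <- as.numeric(trimws(vapply(physMax, edfNum8, "")))
  digMin <- -32768L
  digMax <- 32767L
  scale <- (physMax - physMin) / (digMax - digMin)
  dig <- round(sweep(sweep(x, 1L, physMin), 1L, scale, "/")) + digMin
  dig <- pmin(pmax(dig, digMin), digMax)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edfPad("0", 8L), edfPad("X X X X", 80L), edfPad("Startdate X ptebio", 80L),
    edfPad("01.01.00", 8L), edfPad("00.00.00", 8L),
    edfPad(256L * (1L + nch), 8L), edfPad("", 44L),
    edfPad(nRecords, 8L), edfNum8(recDur), edfPad(nch, 4L)
  )
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste0(vapply(vals, edfPad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(rec@channelLabels, 16L)
  field(rep("", nch), 80L)
  field(rep("uV", nch), 8L)
  writeChar(paste0(vapply(physMin, edfNum8, ""), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(physMax, edfNum8, ""), collapse = ""), con, eos = NULL)
  field(rep(digMin, nch), 8L)
  field(rep(digMax, nch), 8L)
  field(rep("", nch), 80L)
  field(rep(spr, nch), 8L)
  field(rep("", nch), 32L)
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch))
      writeBin(as.integer(dig[ch, idx]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

readEDFHeaderNum <- function(con, width, what = "numeric field") {
  s <- trimws(readChar(con, width, useBytes = TRUE))
  v <- suppressWarnings(as.numeric(s))
  if (is.na(v)) stop("EDF header: unparseable ", what, " ('", s, "')")
  v
}

readEDF <- function(path) {
  if (!file.exists(path)) stop("cannot read EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readChar(con, 8L, useBytes = TRUE)              # version
  readChar(con, 160L, useBytes = TRUE)            # patient + recording id
  readChar(con, 16L, useBytes = TRUE)             # date + time
  readEDFHeaderNum(con, 8L, "header length")
  readChar(con, 44L, useBytes = TRUE)             # reserved
  nRecords <- readEDFHeaderNum(con, 8L, "record count")
  recDur <- readEDFHeaderNum(con, 8L, "record duration")
  nch <- as.integer(readEDFHeaderNum(con, 4L, "signal count"))
  if (nch < 1L) stop("EDF file declares no signals: ", path)

  fields <- function(width) {
    s <- readChar(con, width * nch, useBytes = TRUE)
    trimws(substring(s, (seq_len(nch) - 1L) * width + 1L, seq_len(nch) * width))
  }
  labels <- fields(16L)
  fields(80L)                                     # transducer
  physDim <- fields(8L)
  physMinS <- fields(8L)
  physMaxS <- fields(8L)
  digMinS <- fields(8L)
  digMaxS <- fields(8L)
  fields(80L)                                     # prefiltering
  spr <- as.integer(fields(8L))
  fields(32L)                                     # reserved

  physMin <- suppressWarnings(as.numeric(physMinS))
  physMax <- suppressWarnings(as.numeric(physMaxS))
  digMin <- suppressWarnings(as.numeric(digMinS))
  digMax <- suppressWarnings(as.numeric(digMaxS))
  badHdr <- !is.finite(physMin) | !is.finite(physMax) |
    !is.finite(digMin) | !is.finite(digMax) | digMax == digMin
  if (any(badHdr))
    stop("EDF data integrity: unusable calibration for channel(s): ",
         paste(labels[badHdr], collapse = ", "))
  if (any(is.na(spr)) || any(spr < 1L))
    stop("EDF header: bad samples-per-record field")
  if (length(unique(spr)) != 1L)
    stop("EDF with differing per-signal sampling rates is not supported")
  spr <- spr[1L]
  fs <- spr / recDur

  n <- as.integer(nRecords) * spr
  data <- matrix(0, nrow = nch, ncol = n)
  for (r in seq_len(nRecords)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nch)) {
      v <- readBin(con, integer(), n = spr, size = 2L, endian = "little",
                   signed = TRUE)
      if (length(v) < spr) stop("EDF file truncated: ", path)
      data[ch, idx] <- v
    }
  }
  scale <- (physMax - physMin) / (digMax - digMin)
  data <- sweep(sweep(data, 1L, digMin), 1L, scale, "*")
  data <- sweep(data, 1L, physMin, "+")
  # unit conversion to microvolts where the physical dimension names one
  unitFactor <- c(uV = 1, mV = 1e3, V = 1e6)
  for (ch in seq_len(nch)) {
    f <- unitFactor[physDim[ch]]
    if (!is.na(f)) data[ch, ] <- data[ch, ] * f
  }
  badData <- apply(data, 1L, function(r) any(!is.finite(r)))
  if (any(badData))
    stop("EDF data integrity: non-finite samples in channel(s): ",
         paste(labels[badData], collapse = ", "))
  if (anyDuplicated(labels))
    labels <- make.unique(labels)
  list(data = data, fs = fs, labels = labels)
}
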