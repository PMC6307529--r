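#' Construct an EEG recording
#'
#' @param data numeric channels-by-samples matrix in microvolts. A plain
#'   vector is treated as a single channel.
#' @param fs sampling rate in samples per second.
#' @param channelLabels channel labels; default \code{"C1"}, \code{"C2"}, ...
#' @param t0 start time in seconds (default 0).
#' @return an \code{\linkS4class{EEGRecording}}.
#' @examples
#' rec <- EEGRecording(matrix(rnorm(400), 2, 200), fs = 200)
#' duration(rec)
#' @export
EEGRecording <- function(data, fs, channelLabels = NULL, t0 = 0) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  if (is.null(channelLabels))
    channelLabels <- paste0("C", seq_len(nrow(data)))
  new("EEGRecording", data = data, fs = as.numeric(fs),
      channelLabels = as.character(channelLabels), t0 = as.numeric(t0))
}

#' @describeIn EEGRecording number of channels
#' @param x an \code{EEGRecording}.
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @describeIn EEGRecording number of samples per channel
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

#' @describeIn EEGRecording sampling rate
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@fs)

#' @describeIn EEGRecording channel labels
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @describeIn EEGRecording start time (seconds)
#' @export
setMethod("startTime", "EEGRecording", function(x) x@t0)

#' @describeIn EEGRecording duration (seconds)
#' @export
setMethod("duration", "EEGRecording", function(x) ncol(x@data) / x@fs)

#' @describeIn EEGRecording signal matrix (microvolts)
#' @export
setMethod("signalData", "EEGRecording", function(x) {
  d <- x@data
  rownames(d) <- x@channelLabels
  d
})

setMethod("show", "EEGRecording", function(object) {
  cat("EEGRecording:", nChannels(object), "channel(s) x",
      nSamples(object), "samples @", samplingRate(object), "Hz\n")
  cat("  time span [", startTime(object), ", ",
      startTime(object) + duration(object), ") s\n", sep = "")
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
})

#' Read an EEG recording
#'
#' Reads either standard 16-bit EDF or the package's plain-text
#' \code{csv_matrix} dialect (rows are channels, first line holds the channel
#' labels, and a JSON side-car \code{<path>.json} supplies \code{"fs"} and
#' optionally \code{"t0"}). EDF signals whose physical dimension is V, mV or
#' uV are converted to microvolts.
#'
#' @param path input file path.
#' @param format \code{"edf"} or \code{"csv_matrix"}; default guesses from the
#'   file extension.
#' @return an \code{\linkS4class{EEGRecording}}.
#' @examples
#' rec <- genEEG(eegSimConfig(nChannels = 2, durationS = 2, seed = 1))$recording
#' f <- tempfile(fileext = ".edf")
#' writeEDF(rec, f)
#' rec2 <- readRecording(f)
#' @export
readRecording <- function(path, format = c("auto", "edf", "csv_matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf"
              else "csv_matrix"
  if (!file.exists(path)) stop("cannot read recording: ", path)
  if (format == "edf") {
    p <- readEDF(path)
    EEGRecording(p$data, p$fs, p$labels)
  } else {
    readCsvMatrix(path)
  }
}

readCsvMatrix <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("csv_matrix format error: side-car '", side, "' with {\"fs\": ...} ",
         "is required")
  meta <- jsonlite::fromJSON(side)
  if (is.null(meta$fs))
    stop("csv_matrix format error: 'fs' missing from side-car ", side)
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("csv_matrix format error: need a label row plus one row per channel")
  labels <- trimws(strsplit(lines[1L], ",")[[1L]])
  rows <- lapply(lines[-1L], function(l) as.numeric(strsplit(l, ",")[[1L]]))
  if (length(rows) != length(labels))
    stop("csv_matrix format error: ", length(labels), " labels but ",
         length(rows), " channel rows")
  ns <- unique(lengths(rows))
  if (length(ns) != 1L)
    stop("csv_matrix format error: channel rows differ in length")
  data <- do.call(rbind, rows)
  bad <- apply(data, 1L, function(r) any(!is.finite(r)))
  if (any(bad))
    stop("data integrity: non-finite samples in channel(s): ",
         paste(labels[bad], collapse = ", "))
  t0 <- if (is.null(meta$t0)) 0 else meta$t0
  EEGRecording(data, meta$fs, labels, t0 = t0)
}

#' Write a recording as csv_matrix
#'
#' Plain-text companion of \code{\link{writeEDF}}: first line channel labels,
#' one comma-separated row per channel, sampling rate in a JSON side-car.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param path output path; the side-car is written to \code{<path>.json}.
#' @return \code{path}, invisibly.
#' @export
writeCsvMatrix <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  lines <- c(paste(rec@channelLabels, collapse = ","),
             apply(rec@data, 1L, function(r)
               paste(format(r, digits = 17, trim = TRUE, scientific = FALSE),
                     collapse = ",")))
  writeLines(lines, path)
  jsonlite::write_json(list(fs = rec@fs, t0 = rec@t0),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Extract a time/channel slice of a recording
#'
#' Times are absolute seconds on the recording's own axis; the interval is
#' half-open \code{[tStartS, tEndS)}.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param tStartS,tEndS slice boundaries in seconds, with
#'   \code{t0 <= tStartS < tEndS <= t0 + duration}.
#' @param channels optional channel labels; the output follows the requested
#'   order. Default keeps all channels.
#' @return an \code{\linkS4class{EEGRecording}} with
#'   \code{round((tEndS - tStartS) * fs)} samples and updated \code{t0}.
#' @export
sliceRecording <- function(rec, tStartS, tEndS, channels = NULL) {
  stopifnot(is(rec, "EEGRecording"))
  tMax <- rec@t0 + duration(rec)
  if (!(tStartS >= rec@t0 && tStartS < tEndS && tEndS <= tMax + 1e-9))
    stop("slice out of range: need ", rec@t0, " <= tStartS < tEndS <= ", tMax)
  if (is.null(channels)) channels <- rec@channelLabels
  if (length(channels) == 0L) stop("empty channel selection")
  miss <- setdiff(channels, rec@channelLabels)
  if (length(miss))
    stop("unknown channel(s): ", paste(miss, collapse = ", "))
  i0 <- round((tStartS - rec@t0) * rec@fs)
  n <- round((tEndS - tStartS) * rec@fs)
  rows <- match(channels, rec@channelLabels)
  EEGRecording(rec@data[rows, i0 + seq_len(n), drop = FALSE], rec@fs,
               channels, t0 = rec@t0 + i0 / rec@fs)
}
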