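#' Number of channels in a recording
#' @param x an \code{\linkS4class{EEGRecording}}.
#' @return integer count.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of samples per channel
#' @param x an \code{\linkS4class{EEGRecording}}.
#' @return integer count.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sampling rate in samples per second
#' @param x an object with a sampling rate.
#' @return numeric scalar.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Channel labels
#' @param x an object with labelled channels.
#' @return character vector.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Start time in seconds
#' @param x an \code{\linkS4class{EEGRecording}}.
#' @return numeric scalar.
#' @export
setGeneric("startTime", function(x) standardGeneric("startTime"))

#' Duration in seconds
#' @param x an \code{\linkS4class{EEGRecording}}.
#' @return numeric scalar, \code{nSamples(x) / samplingRate(x)}.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Signal matrix of a recording
#' @param x an \code{\linkS4class{EEGRecording}}.
#' @return channels-by-samples numeric matrix in microvolts.
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' Number of segments in a segment set
#' @param x a \code{\linkS4class{SegmentSet}}.
#' @return integer count.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Per-window values of a profile or result
#' @param x an \code{\linkS4class{MIProfile}} or
#'   \code{\linkS4class{UDCAResult}}.
#' @return numeric vector.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Flagged outlier windows
#' @param x a \code{\linkS4class{UDCAResult}}.
#' @return logical vector, one flag per analysis window.
#' @export
setGeneric("outlierFlags", function(x) standardGeneric("outlierFlags"))

#' Markers of a PVS table
#' @param x a \code{\linkS4class{PVSMarkerTable}}.
#' @return data.frame with columns \code{hemisphere} and \code{caliber_mm}.
#' @export
setGeneric("pvsMarkers", function(x) standardGeneric("pvsMarkers"))

#' Subject identifier
#' @param x a \code{\linkS4class{PVSMarkerTable}}.
#' @return character scalar.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
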