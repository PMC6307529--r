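#' Short-time Fourier spectrogram of one channel
#'
#' Applies the STFT to the raw, unfiltered signal of one channel and scales
#' the squared magnitudes to a one-sided power spectral density in
#' microvolt^2/Hz (interior bins carry the doubled negative-frequency energy,
#' so that the density integrates to the signal power).
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param channel channel label to analyse.
#' @param windowLenS analysis window length in seconds; default 1.
#' @param overlapFrac fractional window overlap in [0, 1); default 0.5.
#' @param taper \code{"hann"} (periodic) or \code{"rect"}.
#' @return a \code{\linkS4class{Spectrogram}}.
#' @examples
#' rec <- EEGRecording(sin(2 * pi * 10 * (0:1999) / 200), fs = 200)
#' sp <- stftSpectrogram(rec, "C1")
#' sp@freqs[which.max(rowMeans(sp@power))]  # 10 Hz
#' @export
stftSpectrogram <- function(rec, channel, windowLenS = 1, overlapFrac = 0.5,
                            taper = c("hann", "rect")) {
  stopifnot(is(rec, "EEGRecording"))
  taper <- match.arg(taper)
  if (!channel %in% rec@channelLabels)
    stop("unknown channel: ", channel)
  if (overlapFrac < 0 || overlapFrac >= 1)
    stop("overlapFrac must lie in [0, 1)")
  x <- rec@data[match(channel, rec@channelLabels), ]
  n <- round(windowLenS * rec@fs)
  if (n < 2) stop("window must span at least 2 samples")
  if (n > length(x)) stop("window longer than recording")
  hop <- max(1L, round(n * (1 - overlapFrac)))
  starts <- seq.int(1L, length(x) - n + 1L, by = hop)
  w <- if (taper == "hann") 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
       else rep(1, n)
  frames <- vapply(starts, function(s) x[s:(s + n - 1L)] * w, numeric(n))
  X <- stats::mvfft(matrix(frames, nrow = n))
  nf <- n %/% 2L + 1L
  p <- Mod(X[seq_len(nf), , drop = FALSE])^2 / (rec@fs * sum(w^2))
  scale <- rep(2, nf)
  scale[1L] <- 1
  if (n %% 2L == 0L) scale[nf] <- 1
  p <- p * scale
  new("Spectrogram",
      power = p,
      freqs = (seq_len(nf) - 1L) * rec@fs / n,
      frameTimes = rec@t0 + (starts - 1L) / rec@fs,
      windowLenS = n / rec@fs,
      overlapFrac = 1 - hop / n,
      channel = channel)
}

setMethod("show", "Spectrogram", function(object) {
  cat("Spectrogram of channel", object@channel, ":",
      length(object@freqs), "freq bins x", length(object@frameTimes),
      "frames\n  window", object@windowLenS, "s, overlap",
      round(100 * object@overlapFrac), "%, freqs up to",
      max(object@freqs), "Hz\n")
})

#' Plot a spectrogram
#'
#' @param x a \code{\linkS4class{Spectrogram}}.
#' @param logPower plot 10*log10(power) when \code{TRUE} (default).
#' @param ... further arguments to \code{\link[graphics]{image}}.
#' @return invisibly, \code{NULL}.
#' @export
setMethod("plot", signature(x = "Spectrogram", y = "missing"),
  function(x, logPower = TRUE, ...) {
    z <- t(x@power)
    if (logPower) z <- 10 * log10(z + .Machine$double.xmin)
    graphics::image(x@frameTimes, x@freqs, z, xlab = "time (s)",
                    ylab = "frequency (Hz)", ...)
    invisible(NULL)
})

trapz <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
}

#' Band power per frame
#'
#' Trapezoidal integral of the one-sided density over a frequency band, per
#' spectrogram frame.
#'
#' @param spec a \code{\linkS4class{Spectrogram}}.
#' @param fLo,fHi band edges in Hz, \code{0 <= fLo < fHi <= max(freqs)}.
#' @return numeric vector of band power (microvolt^2) per frame, with the
#'   frame start times attached as attribute \code{frameTimes}.
#' @export
bandPowerSeries <- function(spec, fLo, fHi) {
  stopifnot(is(spec, "Spectrogram"))
  if (!(fLo >= 0 && fLo < fHi && fHi <= max(spec@freqs) + 1e-9))
    stop("band must satisfy 0 <= fLo < fHi <= ", max(spec@freqs))
  sel <- spec@freqs >= fLo & spec@freqs <= fHi
  if (!any(sel)) stop("empty band: no frequency bins in [", fLo, ", ", fHi, "]")
  f <- spec@freqs[sel]
  out <- apply(spec@power[sel, , drop = FALSE], 2L, function(p) trapz(f, p))
  attr(out, "frameTimes") <- spec@frameTimes
  out
}

#' Total power per frame
#'
#' @param spec a \code{\linkS4class{Spectrogram}}.
#' @return band power over the full frequency axis (see
#'   \code{\link{bandPowerSeries}}).
#' @export
totalPowerSeries <- function(spec)
  bandPowerSeries(spec, 0, max(spec@freqs))

#' Intervals where a series exceeds a threshold
#'
#' Scans a per-frame series for maximal half-open time intervals where the
#' value is strictly above the threshold, discarding intervals shorter than
#' a minimum duration. Used to quantify band-limited activity over time.
#'
#' @param series numeric series, e.g. from \code{\link{bandPowerSeries}} (its
#'   \code{frameTimes} attribute is used when \code{frameTimes} is missing).
#' @param threshold finite threshold; frames with \code{series > threshold}
#'   are inside an event.
#' @param minDurationS minimum event duration in seconds (>= 0).
#' @param frameTimes frame start times; equally spaced.
#' @return data.frame with columns \code{start_s}, \code{end_s}; zero rows
#'   when nothing exceeds the threshold.
#' @export
thresholdEvents <- function(series, threshold, minDurationS = 0,
                            frameTimes = attr(series, "frameTimes")) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (minDurationS < 0) stop("minDurationS must be >= 0")
  if (is.null(frameTimes)) frameTimes <- seq_along(series) - 1
  if (length(frameTimes) != length(series))
    stop("one frame time per series value required")
  spacing <- if (length(frameTimes) > 1L) frameTimes[2L] - frameTimes[1L] else 1
  above <- as.vector(series) > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths * spacing >= minDurationS
  data.frame(start_s = frameTimes[starts[keep]],
             end_s = frameTimes[ends[keep]] + spacing)
}
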