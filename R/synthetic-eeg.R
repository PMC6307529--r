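# Deterministic per-component substreams: one user seed fans out so that
# adding a component never perturbs the draws of another.
componentSeed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483647)
}

#' Configuration of the synthetic EEG generator
#'
#' Defaults emulate long-term clinical/experimental EEG at 200
#' samples/second: a 1/f-like background at 20 microvolt RMS, epileptiform
#' spike-and-slow-wave transients of 300 microvolt peak amplitude and 70 ms
#' sharp phase (clinically typical values), and an inter-channel coupling
#' that ramps from 0 to 0.8 of shared-signal variance toward a seizure onset
#' at the end of the record, so that windowed mutual information rises
#' toward the seizure.
#'
#' @param nChannels number of channels; default 5.
#' @param fs sampling rate in samples/second; default 200.
#' @param durationS recording length in seconds; default 300.
#' @param backgroundExponent spectral exponent of the 1/f^a background;
#'   default 1.
#' @param backgroundRmsUv background RMS amplitude in microvolts; default 20.
#' @param spikeTimesS explicit spike peak times in seconds, or \code{NULL}
#'   to draw them at \code{spikeRatePerMin}.
#' @param spikeRatePerMin spike rate when \code{spikeTimesS} is NULL;
#'   default 4 per minute. Set 0 to disable spikes.
#' @param spikeAmplitudeUv peak amplitude of the sharp phase; default 300.
#' @param spikeWidthMs sharp-phase width in ms (slow wave spans 3x this);
#'   default 70.
#' @param seizureOnsetS optional time toward which coupling ramps; default
#'   \code{NULL} (no seizure in the record). When a ramp is requested
#'   without an onset, the ramp spans the whole record and no seizure
#'   interval is reported.
#' @param couplingRamp length-2 vector: shared-variance fraction at the
#'   start of the record and at the seizure onset, each in [0, 1],
#'   nondecreasing; default \code{c(0, 0)} (uncoupled channels). The
#'   convention for a record approaching seizure is \code{c(0, 0.8)}.
#' @param seed integer seed; every draw derives from it.
#' @return validated list of class \code{"eegSimConfig"}.
#' @export
eegSimConfig <- function(nChannels = 5L, fs = 200, durationS = 300,
                         backgroundExponent = 1, backgroundRmsUv = 20,
                         spikeTimesS = NULL, spikeRatePerMin = 4,
                         spikeAmplitudeUv = 300, spikeWidthMs = 70,
                         seizureOnsetS = NULL,
                         couplingRamp = c(0, 0), seed = 1L) {
  if (nChannels < 1L || fs <= 0 || durationS <= 0)
    stop("nChannels, fs and durationS must be positive")
  if (length(couplingRamp) != 2L || any(couplingRamp < 0) ||
      any(couplingRamp > 1) || couplingRamp[2L] < couplingRamp[1L])
    stop("couplingRamp must be nondecreasing fractions in [0, 1]")
  if (!is.null(spikeTimesS) &&
      (any(spikeTimesS < 0) || any(spikeTimesS >= durationS)))
    stop("all spike times must lie in [0, durationS)")
  if (spikeWidthMs / 1000 * 4 >= durationS)
    stop("infeasible config: spike transient does not fit the recording")
  if (!is.null(seizureOnsetS) &&
      (seizureOnsetS <= 0 || seizureOnsetS > durationS))
    stop("seizureOnsetS must lie in (0, durationS]")
  structure(list(nChannels = as.integer(nChannels), fs = fs,
                 durationS = durationS,
                 backgroundExponent = backgroundExponent,
                 backgroundRmsUv = backgroundRmsUv,
                 spikeTimesS = spikeTimesS,
                 spikeRatePerMin = spikeRatePerMin,
                 spikeAmplitudeUv = spikeAmplitudeUv,
                 spikeWidthMs = spikeWidthMs,
                 seizureOnsetS = seizureOnsetS,
                 couplingRamp = couplingRamp, seed = as.integer(seed)),
            class = "eegSimConfig")
}

# 1/f^a noise of unit RMS via spectral shaping of white Gaussian noise
oneOverFNoise <- function(n, exponent) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1e-12, seq_len(n - 1L))
  f <- pmin(f, n - f)                      # two-sided frequency index
  X <- X * f^(-exponent / 2)
  X[1L] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# epileptiform spike-and-slow-wave template (unit peak amplitude)
spikeTemplate <- function(fs, widthMs) {
  nSharp <- max(2L, round(widthMs / 1000 * fs))
  nSlow <- 3L * nSharp
  c(sin(pi * seq_len(nSharp) / nSharp),
    -0.4 * sin(pi * seq_len(nSlow) / nSlow))
}

#' Generate a synthetic EEG recording with ground truth
#'
#' Produces a multichannel recording whose channels share a common latent
#' 1/f signal with a mixing fraction that follows the configured coupling
#' ramp toward seizure onset, plus independent 1/f background and
#' epileptiform spike-and-slow-wave transients added to all channels with
#' small per-channel jitter. Fully reproducible from the seed.
#'
#' @param cfg an \code{\link{eegSimConfig}}.
#' @return list with \code{recording}
#'   (\code{\linkS4class{EEGRecording}}), \code{spikeTimesS} (ground-truth
#'   spike peak times), and \code{seizureIntervalS} (onset to end, or NULL
#'   when coupling is flat).
#' @examples
#' sim <- genEEG(eegSimConfig(durationS = 60, seed = 7))
#' length(sim$spikeTimesS)
#' @export
genEEG <- function(cfg) {
  stopifnot(inherits(cfg, "eegSimConfig"))
  n <- round(cfg$durationS * cfg$fs)
  nch <- cfg$nChannels

  set.seed(componentSeed(cfg$seed, "background"))
  bg <- vapply(seq_len(nch), function(ch)
    oneOverFNoise(n, cfg$backgroundExponent), numeric(n))
  set.seed(componentSeed(cfg$seed, "latent"))
  z <- oneOverFNoise(n, cfg$backgroundExponent)

  # mixing fraction of shared variance, ramping linearly to seizure onset
  # (or over the whole record when no onset is configured)
  tIdx <- (seq_len(n) - 1L) / cfg$fs
  rampEnd <- if (is.null(cfg$seizureOnsetS)) cfg$durationS
             else cfg$seizureOnsetS
  alpha <- cfg$couplingRamp[1L] +
    (cfg$couplingRamp[2L] - cfg$couplingRamp[1L]) *
    pmin(tIdx / rampEnd, 1)
  data <- t(vapply(seq_len(nch), function(ch)
    cfg$backgroundRmsUv * (sqrt(1 - alpha) * bg[, ch] + sqrt(alpha) * z),
    numeric(n)))

  if (is.null(cfg$spikeTimesS)) {
    set.seed(componentSeed(cfg$seed, "spiketimes"))
    nSpk <- round(cfg$spikeRatePerMin * cfg$durationS / 60)
    spikeTimes <- if (nSpk > 0)
      sort(stats::runif(nSpk, 0.05 * cfg$durationS, 0.95 * cfg$durationS))
    else numeric(0)
  } else spikeTimes <- sort(cfg$spikeTimesS)

  if (length(spikeTimes)) {
    tmpl <- spikeTemplate(cfg$fs, cfg$spikeWidthMs)
    nSharp <- max(2L, round(cfg$spikeWidthMs / 1000 * cfg$fs))
    set.seed(componentSeed(cfg$seed, "spikejitter"))
    for (tS in spikeTimes) {
      # template placed so the sharp-phase peak sits at the stated time
      i0 <- round(tS * cfg$fs) + 1L - nSharp %/% 2L
      for (ch in seq_len(nch)) {
        jit <- sample(-2:2, 1L)
        gain <- stats::runif(1L, 0.8, 1.2)
        idx <- i0 + jit + seq_along(tmpl) - 1L
        ok <- idx >= 1L & idx <= n
        data[ch, idx[ok]] <- data[ch, idx[ok]] +
          cfg$spikeAmplitudeUv * gain * tmpl[ok]
      }
    }
  }
  seizure <- if (!is.null(cfg$seizureOnsetS))
    c(cfg$seizureOnsetS, cfg$durationS) else NULL
  list(recording = EEGRecording(data, cfg$fs),
       spikeTimesS = spikeTimes,
       seizureIntervalS = seizure)
}

#' Map event times to 50\%-overlapping analysis windows
#'
#' Returns the indices of the segments (as produced by
#' \code{\link{segmentRecording}} at the given window size) whose time span
#' contains at least one of the event times.
#'
#' @param eventTimesS event times in seconds.
#' @param nSamples total samples in the recording.
#' @param fs sampling rate.
#' @param windowSize segment length in samples (even).
#' @return sorted integer vector of segment indices.
#' @export
windowsContaining <- function(eventTimesS, nSamples, fs, windowSize) {
  half <- windowSize %/% 2L
  nSeg <- (nSamples - windowSize) %/% half + 1L
  starts <- (seq_len(nSeg) - 1L) * half / fs
  ends <- starts + windowSize / fs
  hit <- vapply(seq_len(nSeg), function(k)
    any(eventTimesS >= starts[k] & eventTimesS < ends[k]), TRUE)
  which(hit)
}
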