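#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG signal. The signal is stored
#' as a channels-by-samples matrix in microvolts together with the sampling
#' rate and a time origin. All analysis functions in the package
#' (\code{\link{stftSpectrogram}}, \code{\link{windowedMI}},
#' \code{\link{runUDCA}}) consume this class.
#'
#' @slot data numeric matrix, \code{n_channels x n_samples}, in microvolts.
#' @slot fs sampling rate in samples per second (> 0).
#' @slot channelLabels character vector of unique channel labels, one per row
#'   of \code{data}.
#' @slot t0 start time of the first sample in seconds (default 0). Sample
#'   \code{k} (0-based) occurs at time \code{t0 + k/fs}; all time intervals in
#'   the package are half-open \code{[start, end)}.
#'
#' @seealso \code{\link{readRecording}}, \code{\link{sliceRecording}},
#'   \code{\link{genEEG}}
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    t0 = "numeric"
  ),
  prototype(t0 = 0)
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be a numeric matrix")
  if (nrow(object@data) < 1L || ncol(object@data) < 1L)
    msg <- c(msg, "recording needs at least one channel and one sample")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@data))
    msg <- c(msg, "one channel label per data row is required")
  if (anyDuplicated(object@channelLabels))
    msg <- c(msg, "channel labels must be unique")
  if (length(object@t0) != 1L || !is.finite(object@t0))
    msg <- c(msg, "t0 must be a single finite number")
  if (anyNA(object@data) || any(!is.finite(object@data))) {
    bad <- object@channelLabels[apply(object@data, 1L,
                                      function(r) any(!is.finite(r)))]
    msg <- c(msg, paste0("non-finite samples in channel(s): ",
                         paste(bad, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Set of 50\%-overlapping EEG segments
#'
#' Ordered windows cut from an \code{\linkS4class{EEGRecording}} with fixed
#' half-window overlap, together with the per-segment flattened feature rows,
#' channel covariance matrices and their SVD pseudo-inverses. Produced by
#' \code{\link{segmentRecording}} and consumed by the diffusion-embedding
#' pipeline.
#'
#' @slot segments list of \code{n_channels x windowSize} matrices.
#' @slot features matrix whose i-th row is segment i flattened channel-major.
#' @slot covariances list of per-segment channel covariance matrices.
#' @slot invCovariances list of SVD pseudo-inverses of \code{covariances}
#'   (empty until \code{\link{segmentCovariances}} is called).
#' @slot windowSize samples per segment (even).
#' @slot fs sampling rate of the source recording.
#' @slot startTimesS segment start times in seconds.
#' @slot channelLabels channel labels of the source recording.
#' @export
setClass("SegmentSet",
  representation(
    segments = "list",
    features = "matrix",
    covariances = "list",
    invCovariances = "list",
    windowSize = "integer",
    fs = "numeric",
    startTimesS = "numeric",
    channelLabels = "character"
  )
)

setValidity("SegmentSet", function(object) {
  msg <- character()
  n <- length(object@segments)
  if (n < 1L) msg <- c(msg, "at least one segment required")
  if (object@windowSize %% 2L != 0L)
    msg <- c(msg, "windowSize must be even (half overlap must be integral)")
  if (nrow(object@features) != n)
    msg <- c(msg, "features must have one row per segment")
  if (length(object@startTimesS) != n)
    msg <- c(msg, "one start time per segment required")
  if (length(msg)) msg else TRUE
})

#' Short-time Fourier spectrogram
#'
#' Time-frequency power representation of one EEG channel, scaled as a
#' one-sided power spectral density (microvolt^2 per Hz). Produced by
#' \code{\link{stftSpectrogram}}.
#'
#' @slot power numeric matrix \code{n_freqs x n_frames}, elementwise >= 0.
#' @slot freqs strictly increasing frequency vector in Hz, up to fs/2.
#' @slot frameTimes frame start times in seconds, spaced
#'   \code{windowLenS * (1 - overlapFrac)}.
#' @slot windowLenS analysis window length in seconds.
#' @slot overlapFrac fractional overlap between consecutive windows, in [0,1).
#' @slot channel label of the analysed channel.
#' @export
setClass("Spectrogram",
  representation(
    power = "matrix",
    freqs = "numeric",
    frameTimes = "numeric",
    windowLenS = "numeric",
    overlapFrac = "numeric",
    channel = "character"
  )
)

setValidity("Spectrogram", function(object) {
  msg <- character()
  if (any(object@power < 0)) msg <- c(msg, "power must be non-negative")
  if (nrow(object@power) != length(object@freqs))
    msg <- c(msg, "one frequency per power row required")
  if (ncol(object@power) != length(object@frameTimes))
    msg <- c(msg, "one frame time per power column required")
  if (length(object@freqs) > 1L && any(diff(object@freqs) <= 0))
    msg <- c(msg, "freqs must be strictly increasing")
  if (length(object@frameTimes) > 1L && any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (object@overlapFrac < 0 || object@overlapFrac >= 1)
    msg <- c(msg, "overlapFrac must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Windowed mutual-information profile
#'
#' Mutual information (bits) between one channel pair, estimated over
#' consecutive non-overlapping windows. Produced by \code{\link{windowedMI}};
#' trend statistics via \code{\link{miTrend}}.
#'
#' @slot values MI per window in bits, elementwise >= 0.
#' @slot windowLenS window length in seconds (default 30).
#' @slot windowStartsS window start times; spacing equals \code{windowLenS}.
#' @slot channelPair the two channel labels.
#' @slot estimator estimator name; currently \code{"histogram"}.
#' @export
setClass("MIProfile",
  representation(
    values = "numeric",
    windowLenS = "numeric",
    windowStartsS = "numeric",
    channelPair = "character",
    estimator = "character"
  ),
  prototype(estimator = "histogram")
)

setValidity("MIProfile", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "MI values must be non-negative")
  if (length(object@windowStartsS) != length(object@values))
    msg <- c(msg, "one start time per value required")
  if (length(object@windowStartsS) > 1L) {
    sp <- diff(object@windowStartsS)
    if (any(abs(sp - object@windowLenS) > 1e-9 * object@windowLenS))
      msg <- c(msg, "windows must be consecutive and non-overlapping")
  }
  if (length(object@channelPair) != 2L)
    msg <- c(msg, "channelPair must hold exactly two labels")
  if (length(msg)) msg else TRUE
})

#' Configuration of the diffusion-component embedding
#'
#' Parameters of \code{\link{runUDCA}}. The segment overlap is fixed at 50\%;
#' the kernel scale default of 10 matches the spread of typical raw EEG
#' feature distances after Mahalanobis normalisation.
#'
#' @slot windowSize samples per segment (even); default 400 (2 s at 200 Hz).
#' @slot overlapFrac fixed at 0.5.
#' @slot kE Gaussian kernel scale, > 0; default 10. The kernel is
#'   \code{exp(-d / (4 * kE))}.
#' @slot svdTol relative singular-value cutoff for covariance pseudo-inversion.
#' @slot nEigenvectors eigenpairs retained; must be >= 4 since the first
#'   (constant) eigenvector is excluded from candidate embeddings.
#' @slot embedDim fixed at 3.
#' @slot outlierRule \code{"mad"} or \code{"quantile"}.
#' @slot outlierParam multiplier (mad rule) or top fraction (quantile rule).
#' @slot maxLag cross-correlation QC lag limit in samples.
#' @seealso \code{\link{udcaConfig}}
#' @export
setClass("UDCAConfig",
  representation(
    windowSize = "integer",
    overlapFrac = "numeric",
    kE = "numeric",
    svdTol = "numeric",
    nEigenvectors = "integer",
    embedDim = "integer",
    outlierRule = "character",
    outlierParam = "numeric",
    maxLag = "integer"
  )
)

setValidity("UDCAConfig", function(object) {
  msg <- character()
  if (object@overlapFrac != 0.5)
    msg <- c(msg, "overlapFrac is fixed at 0.5")
  if (object@kE <= 0) msg <- c(msg, "kE must be positive")
  if (object@svdTol <= 0 || object@svdTol >= 1)
    msg <- c(msg, "svdTol must lie in (0, 1)")
  if (object@embedDim != 3L) msg <- c(msg, "embedDim is fixed at 3")
  if (object@nEigenvectors < object@embedDim + 1L)
    msg <- c(msg, "nEigenvectors must be at least embedDim + 1")
  if (!object@outlierRule %in% c("mad", "quantile"))
    msg <- c(msg, "outlierRule must be 'mad' or 'quantile'")
  if (object@outlierParam <= 0) msg <- c(msg, "outlierParam must be positive")
  if (object@windowSize %% 2L != 0L || object@windowSize < 2L)
    msg <- c(msg, "windowSize must be an even integer >= 2")
  if (length(msg)) msg else TRUE
})

#' Result of the diffusion-component embedding pipeline
#'
#' Holds every intermediate of \code{\link{runUDCA}}: consecutive-segment
#' Mahalanobis distances, the affinity kernel, the two normalisation row-sum
#' vectors, the sorted eigendecomposition of the twice-normalised operator,
#' the point-cloud (diffusion) coordinates, the Nystrom self-extension, all
#' candidate 3-D embeddings with their spreads, the selected embedding, and
#' per-window outlier scores and flags.
#'
#' @slot distances consecutive-segment Mahalanobis quadratic forms
#'   (length \code{n_segments - 1}).
#' @slot kernel affinity matrix A, entries in (0, 1], unit diagonal.
#' @slot rowSums1,rowSums2 stage-one and stage-two normalisation row sums.
#' @slot eigenvalues eigenvalues of the normalised operator, descending;
#'   leading value 1 within numerical tolerance.
#' @slot eigenvectors orthonormal eigenvectors (columns), same order.
#' @slot pointClouds diffusion coordinates: eigenvectors scaled by
#'   \code{1/sqrt(rowSums2)}; leading column constant.
#' @slot psi Nystrom self-extension of the training segments (equals
#'   \code{pointClouds} up to numerical error).
#' @slot embeddingTriples integer matrix, one candidate eigenvector index
#'   triple per row (indices >= 2).
#' @slot spreadPerEmbedding mean Euclidean distance to the centre of mass for
#'   each candidate triple.
#' @slot selectedTriple the triple with maximal spread (lexicographic
#'   tie-break).
#' @slot selectedCoordinates n_segments x 3 eigenvalue-weighted diffusion
#'   coordinates of the selected embedding.
#' @slot outlierScores per-window Euclidean distance to the embedding's
#'   centre of mass.
#' @slot outlierFlags logical flags per window.
#' @slot windowStartsS segment start times in seconds (maps flags to time).
#' @slot qc per-channel-pair cross-correlation QC summary.
#' @slot config the \code{\linkS4class{UDCAConfig}} used.
#' @export
setClass("UDCAResult",
  representation(
    distances = "numeric",
    kernel = "matrix",
    rowSums1 = "numeric",
    rowSums2 = "numeric",
    eigenvalues = "numeric",
    eigenvectors = "matrix",
    pointClouds = "matrix",
    psi = "matrix",
    embeddingTriples = "matrix",
    spreadPerEmbedding = "numeric",
    selectedTriple = "integer",
    selectedCoordinates = "matrix",
    outlierScores = "numeric",
    outlierFlags = "logical",
    windowStartsS = "numeric",
    qc = "data.frame",
    config = "UDCAConfig"
  )
)

setValidity("UDCAResult", function(object) {
  msg <- character()
  if (length(object@eigenvalues) &&
      is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be sorted descending")
  if (length(object@selectedTriple) == 3L && any(object@selectedTriple < 2L))
    msg <- c(msg, "embedding triples must exclude eigenvector index 1")
  if (length(msg)) msg else TRUE
})

#' Per-subject perivascular-space marker table
#'
#' All PVSs marked for one subject on T2-weighted MRI: one marker per row with
#' its hemisphere and caliber (mm), plus subject metadata. Calibers are
#' constrained to the reliable marking range [0.5, 3) mm; the loader
#' (\code{\link{readPvsTable}}) drops out-of-range markers with a report.
#'
#' @slot subjectId subject identifier.
#' @slot group \code{"TBI"} or \code{"control"}.
#' @slot ageYears non-negative age in years.
#' @slot sex \code{"M"} or \code{"F"}.
#' @slot markers data.frame with columns \code{hemisphere}
#'   (\code{"right"}/\code{"left"}) and \code{caliber_mm}.
#' @seealso \code{\link{subjectAsymmetry}}, \code{\link{cohortReport}}
#' @export
setClass("PVSMarkerTable",
  representation(
    subjectId = "character",
    group = "character",
    ageYears = "numeric",
    sex = "character",
    markers = "data.frame"
  )
)

setValidity("PVSMarkerTable", function(object) {
  msg <- character()
  if (!object@group %in% c("TBI", "control"))
    msg <- c(msg, "group must be 'TBI' or 'control'")
  if (!object@sex %in% c("M", "F"))
    msg <- c(msg, "sex must be 'M' or 'F'")
  if (length(object@ageYears) != 1L || object@ageYears < 0)
    msg <- c(msg, "ageYears must be a single non-negative number")
  if (!all(c("hemisphere", "caliber_mm") %in% names(object@markers)))
    msg <- c(msg, "markers needs columns hemisphere and caliber_mm")
  else {
    if (!all(object@markers$hemisphere %in% c("right", "left")))
      msg <- c(msg, "hemisphere must be 'right' or 'left'")
    cal <- object@markers$caliber_mm
    if (length(cal) && (any(cal < 0.5) || any(cal >= 3)))
      msg <- c(msg, "caliber_mm must lie in [0.5, 3) mm")
  }
  if (length(msg)) msg else TRUE
})
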