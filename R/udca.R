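#' Configuration constructor for the diffusion-component pipeline
#'
#' @param windowSize samples per segment (even); default 400, i.e. 2 s at
#'   200 samples/second.
#' @param kE Gaussian kernel scale (> 0); default 10, matched to the spread
#'   of Mahalanobis distances of raw EEG windows.
#' @param svdTol relative singular-value cutoff for covariance
#'   pseudo-inversion; default 1e-8.
#' @param nEigenvectors eigenpairs retained (>= 4); default 8.
#' @param outlierRule \code{"mad"} or \code{"quantile"}; default
#'   \code{"quantile"}.
#' @param outlierParam MAD multiplier or flagged top fraction; default 0.05.
#' @param maxLag cross-correlation QC lag limit in samples; default 32.
#' @return a validated \code{\linkS4class{UDCAConfig}}.
#' @export
udcaConfig <- function(windowSize = 400L, kE = 10, svdTol = 1e-8,
                       nEigenvectors = 8L, outlierRule = "quantile",
                       outlierParam = 0.05, maxLag = 32L) {
  new("UDCAConfig", windowSize = as.integer(windowSize), overlapFrac = 0.5,
      kE = kE, svdTol = svdTol, nEigenvectors = as.integer(nEigenvectors),
      embedDim = 3L, outlierRule = outlierRule, outlierParam = outlierParam,
      maxLag = as.integer(maxLag))
}

#' Cut a recording into 50\%-overlapping segments
#'
#' Divides the signal matrix into submatrices of \code{windowSize} samples
#' overlapped by half a window (for smoothing); a trailing remainder shorter
#' than half a window is dropped. The i-th feature row is segment i flattened
#' channel-major (channel 1's samples, then channel 2's, ...).
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param windowSize samples per segment; even, \code{2 <= windowSize <=
#'   nSamples(rec)}.
#' @return a \code{\linkS4class{SegmentSet}} with
#'   \code{floor((nSamples - windowSize) / (windowSize/2)) + 1} segments.
#' @export
segmentRecording <- function(rec, windowSize) {
  stopifnot(is(rec, "EEGRecording"))
  windowSize <- as.integer(windowSize)
  if (windowSize %% 2L != 0L)
    stop("windowSize must be even (half overlap must be integral)")
  if (windowSize < 2L || windowSize > nSamples(rec))
    stop("windowSize must lie in [2, ", nSamples(rec), "]")
  half <- windowSize %/% 2L
  nSeg <- (nSamples(rec) - windowSize) %/% half + 1L
  starts <- (seq_len(nSeg) - 1L) * half
  segs <- lapply(starts, function(s)
    rec@data[, s + seq_len(windowSize), drop = FALSE])
  feats <- t(vapply(segs, function(m) as.vector(t(m)),
                    numeric(nrow(rec@data) * windowSize)))
  new("SegmentSet", segments = segs, features = feats,
      covariances = list(), invCovariances = list(),
      windowSize = windowSize, fs = rec@fs,
      startTimesS = rec@t0 + starts / rec@fs,
      channelLabels = rec@channelLabels)
}

#' @describeIn segmentRecording number of segments
#' @param x a \code{SegmentSet}.
#' @export
setMethod("nSegments", "SegmentSet", function(x) length(x@segments))

setMethod("show", "SegmentSet", function(object) {
  cat("SegmentSet:", nSegments(object), "segments of", object@windowSize,
      "samples (50% overlap),", length(object@channelLabels), "channel(s)\n")
})

# SVD pseudo-inverse with relative singular-value cutoff
pinvSVD <- function(m, tol) {
  s <- svd(m)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Attach channel covariances and pseudo-inverses to a segment set
#'
#' Computes each segment's time-based channel covariance matrix and its SVD
#' pseudo-inverse (singular values below \code{svdTol * sigma_max} are
#' zeroed). A flat, zero-variance segment yields a zero pseudo-inverse with a
#' warning; its distance contributions are 0.
#'
#' @param seg a \code{\linkS4class{SegmentSet}}.
#' @param svdTol relative cutoff in (0, 1).
#' @return the segment set with \code{covariances} and \code{invCovariances}
#'   populated.
#' @export
segmentCovariances <- function(seg, svdTol = 1e-8) {
  stopifnot(is(seg, "SegmentSet"))
  if (svdTol <= 0 || svdTol >= 1) stop("svdTol must lie in (0, 1)")
  covs <- lapply(seg@segments, function(m) stats::cov(t(m)))
  flat <- vapply(covs, function(cm) max(abs(cm)) < .Machine$double.eps, TRUE)
  if (any(flat))
    warning("zero-variance segment(s): ",
            paste(which(flat), collapse = ", "),
            "; their pseudo-inverse is the zero matrix")
  seg@covariances <- covs
  seg@invCovariances <- lapply(covs, pinvSVD, tol = svdTol)
  seg
}

#' Cross-correlation quality control across channels
#'
#' For every channel pair and segment, the maximum over lags (up to
#' \code{maxLag}) of the absolute normalized cross-correlation is computed
#' and summarized per pair as the median across segments. This is
#' report-only: pairs below \code{floor} are flagged with a warning, never
#' dropped. Zero-variance segments are excluded from the median.
#'
#' @param seg a \code{\linkS4class{SegmentSet}}.
#' @param maxLag lag limit in samples, \code{< windowSize}.
#' @param floor warn when a pair's summary falls below this; default 0.
#' @return data.frame with columns \code{chA}, \code{chB},
#'   \code{maxAbsCC} (median across segments).
#' @export
qcCrossCorrelation <- function(seg, maxLag = 32L, floor = 0) {
  stopifnot(is(seg, "SegmentSet"))
  if (maxLag >= seg@windowSize)
    stop("maxLag must be smaller than the window size")
  nch <- length(seg@channelLabels)
  pairs <- utils::combn(nch, 2L)
  res <- apply(pairs, 2L, function(pr) {
    vals <- vapply(seg@segments, function(m) {
      a <- m[pr[1L], ]; b <- m[pr[2L], ]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
      cc <- stats::ccf(a, b, lag.max = maxLag, plot = FALSE,
                       demean = TRUE)$acf
      max(abs(cc))
    }, 0)
    stats::median(vals, na.rm = TRUE)
  })
  out <- data.frame(chA = seg@channelLabels[pairs[1L, ]],
                    chB = seg@channelLabels[pairs[2L, ]],
                    maxAbsCC = res, stringsAsFactors = FALSE)
  low <- out$maxAbsCC < floor
  if (any(low, na.rm = TRUE))
    warning("low cross-correlation for pair(s): ",
            paste(out$chA[low], out$chB[low], sep = "-", collapse = ", "))
  out
}

# Pairwise (or consecutive-only) Mahalanobis quadratic forms between
# segments: d(i,j) = mean_t delta_t' Sbar delta_t, with delta the per-sample
# channel difference and Sbar the average of the two segments'
# pseudo-inverse channel covariances. For segments differing by a constant
# per-channel offset this reduces to the offset's quadratic form.
segmentDistance <- function(seg, i, j) {
  d <- seg@segments[[i]] - seg@segments[[j]]
  m <- (seg@invCovariances[[i]] + seg@invCovariances[[j]]) / 2
  sum((m %*% d) * d) / ncol(d)
}

#' Mahalanobis distances between consecutive segments
#'
#' The covariance-weighted quadratic form between consecutive segment rows
#' of the feature matrix, using the SVD pseudo-inverse channel covariances
#' (average of the two segments' inverses), averaged over the window's
#' samples.
#'
#' @param seg a \code{\linkS4class{SegmentSet}}; covariances are computed on
#'   demand.
#' @param svdTol relative SVD cutoff, used if covariances are missing.
#' @return non-negative numeric vector of length \code{nSegments - 1}.
#' @export
mahalanobisMetric <- function(seg, svdTol = 1e-8) {
  stopifnot(is(seg, "SegmentSet"))
  if (length(seg@invCovariances) == 0L)
    seg <- segmentCovariances(seg, svdTol)
  n <- nSegments(seg)
  if (n < 2L) return(numeric(0))
  vapply(seq_len(n - 1L), function(i) segmentDistance(seg, i, i + 1L), 0)
}

pairwiseMahalanobis <- function(seg) {
  n <- nSegments(seg)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    mi <- seg@invCovariances[[i]]
    si <- seg@segments[[i]]
    for (j in (i + 1L):n) {
      del <- si - seg@segments[[j]]
      m <- (mi + seg@invCovariances[[j]]) / 2
      d[i, j] <- d[j, i] <- sum((m %*% del) * del) / ncol(del)
    }
  }
  d
}

#' Gaussian affinity kernel from Mahalanobis distances
#'
#' \eqn{A = \exp(-d / (4 k_e))} elementwise. With \code{d} a pairwise
#' distance matrix the diagonal is exactly 1 and entries lie in (0, 1].
#'
#' @param d non-negative distances (vector or matrix).
#' @param kE kernel scale, > 0; default 10.
#' @return same shape as \code{d}.
#' @export
affinityKernel <- function(d, kE = 10) {
  if (kE <= 0) stop("kE must be positive")
  if (any(d < 0)) stop("negative distances violate the metric")
  exp(-d / (4 * kE))
}

#' Two-stage normalised diffusion eigendecomposition
#'
#' Normalises the affinity kernel twice (divide by sqrt of the row sums on
#' both sides, square the result, repeat), eigendecomposes the final
#' symmetric operator, sorts eigenpairs in descending order and rescales the
#' eigenvectors by \code{1/sqrt(rowSums2)} into point-cloud (diffusion)
#' coordinates. The leading eigenvalue of the normalised operator is 1 and
#' its point-cloud vector constant; the full spectrum lies in [0, 1].
#'
#' @param A square symmetric affinity kernel, entries in (0, 1].
#' @param nEigenvectors eigenpairs to retain.
#' @return list with \code{eigenvalues}, \code{eigenvectors} (orthonormal
#'   columns of the symmetric operator), \code{pointClouds}, \code{rowSums1},
#'   \code{rowSums2}, and the stage matrices \code{A1}, \code{A2}.
#' @export
diffusionDecomposition <- function(A, nEigenvectors = 8L) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("A must be a square matrix")
  if (max(abs(A - t(A))) > 1e-8 * max(abs(A)))
    stop("A must be symmetric within tolerance")
  if (any(A <= 0) || any(A > 1 + 1e-12))
    stop("kernel entries must lie in (0, 1]")
  A <- (A + t(A)) / 2
  n <- nrow(A)
  nEigenvectors <- min(as.integer(nEigenvectors), n)

  j1 <- rowSums(A)
  s1 <- sqrt(j1)
  A1 <- A / tcrossprod(s1)
  W1 <- A1 %*% A1
  j2 <- rowSums(W1)
  s2 <- sqrt(j2)
  A2 <- W1 / tcrossprod(s2)
  W2 <- A2 %*% A2

  e <- eigen((W2 + t(W2)) / 2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)
  keep <- ord[seq_len(nEigenvectors)]
  V <- e$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (k in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, k]))
    if (V[piv, k] < 0) V[, k] <- -V[, k]
  }
  list(eigenvalues = e$values[keep],
       eigenvectors = V,
       pointClouds = V / s2,
       rowSums1 = j1, rowSums2 = j2, A1 = A1, A2 = A2)
}

# Stage-normalised affinity rows for held-out points: raw kernel rows vs the
# training set are pushed through the same two-stage construction, yielding
# held-out rows of W1 (the row-stochastic stage-two operator's numerator).
extensionRows <- function(kernelRows, decomp) {
  if (is.vector(kernelRows)) kernelRows <- matrix(kernelRows, nrow = 1L)
  j1y <- rowSums(kernelRows)
  if (any(j1y <= 0)) stop("zero kernel row sum for held-out segment(s): ",
                          paste(which(j1y <= 0), collapse = ", "))
  B1 <- kernelRows / (sqrt(j1y) %o% sqrt(decomp$rowSums1))
  B1 %*% decomp$A1
}

#' Nystrom extension of the embedding to held-out segments
#'
#' Assigns diffusion coordinates to segments not used in the
#' eigendecomposition. The held-out raw affinity rows (same metric and
#' kernel scale as training) are normalised through the same two stages,
#' made row-stochastic by their row sums \eqn{\omega}, multiplied by the
#' point-cloud eigenvectors and divided by the square root of each
#' eigenvalue. Extending an in-sample segment reproduces its in-sample
#' coordinates exactly up to numerical error.
#'
#' @param kernelRows m x n matrix (or length-n vector) of raw affinities
#'   between m held-out segments and the n training segments.
#' @param decomp result of \code{\link{diffusionDecomposition}}.
#' @param nCoords extended coordinates requested; at most the retained
#'   eigenpairs.
#' @return list with \code{psi} (m x nCoords extended coordinates; column 1
#'   is the trivial constant), \code{psi1}, \code{psi2} (the coordinates for
#'   the two largest non-trivial eigenvalues, i.e. columns 2 and 3), and
#'   \code{omega} (row sums of the normalised held-out block).
#' @export
nystromExtension <- function(kernelRows, decomp,
                             nCoords = length(decomp$eigenvalues)) {
  if (nCoords > length(decomp$eigenvalues))
    stop("requested more extended coordinates than retained eigenpairs")
  B <- extensionRows(kernelRows, decomp)
  omega <- rowSums(B)
  if (any(omega <= 0))
    stop("zero row sum (segment infinitely far) for held-out segment(s): ",
         paste(which(omega <= 0), collapse = ", "))
  Bn <- B / omega
  lam <- decomp$eigenvalues[seq_len(nCoords)]
  if (any(lam <= 0))
    stop("cannot extend along eigenpairs with non-positive eigenvalue")
  psi <- (Bn %*% decomp$pointClouds[, seq_len(nCoords), drop = FALSE]) %*%
    diag(1 / sqrt(lam), nCoords)
  list(psi = psi,
       psi1 = if (nCoords >= 2L) psi[, 2L] else NULL,
       psi2 = if (nCoords >= 3L) psi[, 3L] else NULL,
       omega = omega)
}

#' Select the 3-D embedding with maximal spread
#'
#' Enumerates all 3-subsets of eigenvector indices >= 2 (the first,
#' constant eigenvector is excluded), computes each candidate embedding's
#' spread -- the mean Euclidean distance of its points from their centre of
#' mass -- and returns the triple with maximal spread. Ties break to the
#' lexicographically smallest triple.
#'
#' When eigenvalues are supplied, candidate coordinates are the
#' eigenvalue-weighted diffusion coordinates \eqn{\lambda_k \phi_k} (the
#' diffusion-distance embedding). Without the weighting, trailing
#' eigenvectors whose eigenvalues are orders of magnitude below the leading
#' non-trivial one -- numerically near-degenerate and localised on single
#' windows -- acquire macroscopic spread through the \code{1/sqrt(rowSums2)}
#' scaling and can hijack the selection.
#'
#' @param pointClouds matrix of point-cloud coordinates (columns are
#'   eigenvector indices, >= 4 columns).
#' @param eigenvalues optional vector of matching eigenvalues; when given,
#'   column k is weighted by \code{eigenvalues[k]} before spread evaluation.
#' @return list with \code{triple} (integer indices), \code{coordinates}
#'   (n x 3, on the same scale used for spread evaluation), \code{spread},
#'   and per-candidate \code{triples} / \code{spreads}.
#' @export
selectEmbedding <- function(pointClouds, eigenvalues = NULL) {
  nv <- ncol(pointClouds)
  if (nv < 4L) stop("need at least 4 eigenvectors (first is excluded)")
  coords <- if (is.null(eigenvalues)) pointClouds
            else sweep(pointClouds, 2L, eigenvalues[seq_len(nv)], "*")
  triples <- utils::combn(2L:nv, 3L)
  spreads <- apply(triples, 2L, function(tr)
    embeddingSpread(coords[, tr, drop = FALSE]))
  best <- which.max(spreads)  # combn order is lexicographic; first max wins
  list(triple = as.integer(triples[, best]),
       coordinates = coords[, triples[, best], drop = FALSE],
       spread = spreads[best],
       triples = t(triples), spreads = spreads)
}

embeddingSpread <- function(coords) {
  centre <- colMeans(coords)
  mean(sqrt(rowSums(sweep(coords, 2L, centre)^2)))
}

#' Outlier scores and flags in an embedding
#'
#' Scores each embedded window by its Euclidean distance from the centre of
#' mass. The \code{"mad"} rule flags scores above
#' \code{median + param * mad} (scaled MAD, \code{\link[stats]{mad}}); the
#' \code{"quantile"} rule flags the \code{ceiling(param * n)} highest scores.
#'
#' @param coords n x d embedding coordinates, n >= 3.
#' @param rule \code{"mad"} or \code{"quantile"}.
#' @param param MAD multiplier, or top fraction in (0, 1].
#' @return list with \code{scores} and logical \code{flags}.
#' @export
outlierScores <- function(coords, rule = c("mad", "quantile"), param = 3) {
  rule <- match.arg(rule)
  if (param <= 0) stop("param must be positive")
  if (nrow(coords) < 3L) stop("need at least 3 embedded points")
  centre <- colMeans(coords)
  scores <- sqrt(rowSums(sweep(coords, 2L, centre)^2))
  flags <- if (rule == "mad") {
    scores > stats::median(scores) + param * stats::mad(scores)
  } else {
    if (param > 1) stop("quantile param must lie in (0, 1]")
    # epsilon guards against param*n landing a hair above an integer
    k <- ceiling(param * length(scores) - 1e-9)
    rank(-scores, ties.method = "first") <= k
  }
  list(scores = scores, flags = flags)
}

#' Run the full diffusion-component pipeline on a recording
#'
#' Segments the recording into 50\%-overlapping windows, computes channel
#' covariances and their SVD pseudo-inverses, builds the pairwise
#' Mahalanobis-metric Gaussian kernel, eigendecomposes the twice-normalised
#' diffusion operator, enumerates all candidate 3-D embeddings from
#' eigenvectors >= 2, selects the one with maximal point spread, and flags
#' outlier windows. The pipeline is deterministic: identical inputs give
#' bitwise-identical results.
#'
#' @param rec an \code{\linkS4class{EEGRecording}} long enough for at least
#'   \code{embedDim + 2} segments.
#' @param config a \code{\linkS4class{UDCAConfig}}; default
#'   \code{udcaConfig()}.
#' @param verbose log the QC summary, selected triple, spread and flagged
#'   windows; default \code{FALSE}.
#' @return a \code{\linkS4class{UDCAResult}}.
#' @examples
#' sim <- genEEG(eegSimConfig(nChannels = 3, durationS = 30, seed = 1))
#' res <- runUDCA(sim$recording, udcaConfig(windowSize = 200))
#' which(outlierFlags(res))
#' @export
runUDCA <- function(rec, config = udcaConfig(), verbose = FALSE) {
  stopifnot(is(rec, "EEGRecording"), is(config, "UDCAConfig"))
  validObject(config)
  seg <- withStage("segment", segmentRecording(rec, config@windowSize))
  if (nSegments(seg) < config@embedDim + 2L)
    stop("udca: recording too short; need at least ", config@embedDim + 2L,
         " segments, got ", nSegments(seg))
  qc <- withStage("qc_cross_correlation",
                  qcCrossCorrelation(seg, maxLag = config@maxLag))
  seg <- withStage("covariances", segmentCovariances(seg, config@svdTol))
  consec <- withStage("mahalanobis_metric", mahalanobisMetric(seg))
  dPair <- withStage("mahalanobis_metric", pairwiseMahalanobis(seg))
  A <- withStage("affinity_kernel", affinityKernel(dPair, config@kE))
  dec <- withStage("diffusion_decomposition",
                   diffusionDecomposition(A, config@nEigenvectors))
  ext <- withStage("nystrom_extension", nystromExtension(A, dec))
  sel <- withStage("select_embedding",
                   selectEmbedding(dec$pointClouds, dec$eigenvalues))
  out <- withStage("outlier_scores",
                   outlierScores(sel$coordinates, config@outlierRule,
                                 config@outlierParam))
  if (verbose) {
    message("udca QC (median max |cross-correlation| per channel pair):")
    for (i in seq_len(nrow(qc)))
      message(sprintf("  %s-%s: %.3f", qc$chA[i], qc$chB[i], qc$maxAbsCC[i]))
    message("udca: selected eigenvector triple (",
            paste(sel$triple, collapse = ", "), "), spread ",
            signif(sel$spread, 4))
    message("udca: flagged windows start at ",
            paste(signif(seg@startTimesS[out$flags], 6), collapse = ", "),
            " s")
  }
  new("UDCAResult",
      distances = consec, kernel = A,
      rowSums1 = dec$rowSums1, rowSums2 = dec$rowSums2,
      eigenvalues = dec$eigenvalues, eigenvectors = dec$eigenvectors,
      pointClouds = dec$pointClouds, psi = ext$psi,
      embeddingTriples = sel$triples, spreadPerEmbedding = sel$spreads,
      selectedTriple = sel$triple, selectedCoordinates = sel$coordinates,
      outlierScores = out$scores, outlierFlags = out$flags,
      windowStartsS = seg@startTimesS, qc = qc, config = config)
}

withStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("udca stage '", stage, "': ", conditionMessage(e), call. = FALSE))
}

#' @describeIn runUDCA logical outlier flags per analysis window
#' @param x a \code{UDCAResult}.
#' @export
setMethod("outlierFlags", "UDCAResult", function(x) x@outlierFlags)

#' @describeIn runUDCA per-window outlier scores
#' @export
setMethod("profileValues", "UDCAResult", function(x) x@outlierScores)

setMethod("show", "UDCAResult", function(object) {
  cat("UDCAResult:", length(object@windowStartsS), "windows,",
      length(object@eigenvalues), "retained eigenpairs\n")
  cat("  selected embedding (", paste(object@selectedTriple, collapse = ", "),
      "), spread ", signif(max(object@spreadPerEmbedding), 4), "\n", sep = "")
  cat("  flagged windows:", sum(object@outlierFlags), "of",
      length(object@outlierFlags), "\n")
})
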