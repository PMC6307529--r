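#' Histogram plug-in mutual information
#'
#' Plug-in estimate of the mutual information between two equal-length
#' samples, in bits, from their joint 2-D histogram with equal-width bins
#' spanning each vector's observed range:
#' \deqn{\hat I = \sum_{ij} p_{ij} \log_2 \frac{p_{ij}}{p_{i\cdot} p_{\cdot j}}}
#' over non-empty cells. The estimate is non-negative by construction and
#' exactly 0 when either input is constant. It is invariant under strictly
#' increasing affine rescaling of either input and symmetric in its
#' arguments.
#'
#' @param x,y numeric vectors of equal length \code{>= nBins}.
#' @param nBins bins per axis, \code{>= 2}; default 16.
#' @return mutual information in bits (scalar, >= 0).
#' @examples
#' x <- rep(1:4, each = 25)
#' mutualInformation(x, x, nBins = 4)  # H(X) = 2 bits
#' @export
mutualInformation <- function(x, y, nBins = 16L) {
  if (length(x) != length(y))
    stop("x and y must have equal length")
  if (nBins < 2L) stop("nBins must be >= 2")
  if (length(x) < nBins)
    stop("need at least nBins observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  rx <- range(x); ry <- range(y)
  if (rx[1L] == rx[2L] || ry[1L] == ry[2L]) return(0)
  bin <- function(v, r) pmin(1L + floor((v - r[1L]) / (r[2L] - r[1L]) * nBins),
                             nBins)
  joint <- tabulate((bin(x, rx) - 1L) * nBins + bin(y, ry), nBins * nBins)
  p <- joint / length(x)
  pm <- matrix(p, nBins, nBins)         # rows: y bins, cols: x bins
  px <- colSums(pm); py <- rowSums(pm)
  nz <- pm > 0
  mi <- sum(pm[nz] * log2(pm[nz] / (outer(py, px)[nz])))
  max(mi, 0)
}

#' Windowed mutual information between two channels
#'
#' Estimates mutual information over consecutive, non-overlapping windows
#' (default 30 s), one value per complete window in temporal order; a
#' trailing partial window is dropped. Identical channel labels are allowed
#' (the profile is then the windowed self-information) but flagged with a
#' message.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param chA,chB channel labels.
#' @param windowLenS window length in seconds; default 30.
#' @param nBins histogram bins per axis; default 16.
#' @return an \code{\linkS4class{MIProfile}}.
#' @seealso \code{\link{miTrend}}
#' @export
windowedMI <- function(rec, chA, chB, windowLenS = 30, nBins = 16L) {
  stopifnot(is(rec, "EEGRecording"))
  miss <- setdiff(c(chA, chB), rec@channelLabels)
  if (length(miss)) stop("unknown channel(s): ", paste(miss, collapse = ", "))
  if (chA == chB)
    message("windowedMI: identical channels; profile is windowed self-MI")
  w <- round(windowLenS * rec@fs)
  nWin <- nSamples(rec) %/% w
  if (nWin < 1L) stop("recording shorter than one window")
  a <- rec@data[match(chA, rec@channelLabels), ]
  b <- rec@data[match(chB, rec@channelLabels), ]
  vals <- vapply(seq_len(nWin), function(k) {
    idx <- ((k - 1L) * w + 1L):(k * w)
    mutualInformation(a[idx], b[idx], nBins)
  }, 0)
  new("MIProfile", values = vals, windowLenS = w / rec@fs,
      windowStartsS = rec@t0 + (seq_len(nWin) - 1L) * w / rec@fs,
      channelPair = c(chA, chB), estimator = "histogram")
}

#' @describeIn windowedMI per-window MI values (bits)
#' @param x an \code{MIProfile}.
#' @export
setMethod("profileValues", "MIProfile", function(x) x@values)

setMethod("show", "MIProfile", function(object) {
  cat("MIProfile", paste(object@channelPair, collapse = " vs "), ":",
      length(object@values), "windows of", object@windowLenS, "s\n")
  cat(sprintf("  MI range [%.4g, %.4g] bits (%s estimator)\n",
              min(object@values), max(object@values), object@estimator))
})

#' Plot an MI profile over time
#' @param x an \code{\linkS4class{MIProfile}}.
#' @param ... further arguments to \code{\link[graphics]{plot}}.
#' @return invisibly, \code{NULL}.
#' @export
setMethod("plot", signature(x = "MIProfile", y = "missing"), function(x, ...) {
  graphics::plot(x@windowStartsS, x@values, type = "b", xlab = "time (s)",
                 ylab = "mutual information (bits)",
                 main = paste(x@channelPair, collapse = " vs "), ...)
  invisible(NULL)
})

#' Trend of a windowed MI profile
#'
#' Quantifies how inter-channel dependence changes over time (e.g. toward a
#' seizure): the least-squares slope of MI against window index and the
#' Spearman rank correlation with its p-value.
#'
#' @param profile an \code{\linkS4class{MIProfile}} with >= 3 windows.
#' @return list with \code{slope} (bits per window), \code{rho} (Spearman),
#'   and \code{pValue}.
#' @export
miTrend <- function(profile) {
  stopifnot(is(profile, "MIProfile"))
  v <- profile@values
  if (length(v) < 3L) stop("need at least 3 windows for a trend")
  idx <- seq_along(v)
  slope <- stats::cov(idx, v) / stats::var(idx)
  if (stats::sd(v) == 0)
    return(list(slope = 0, rho = NA_real_, pValue = NA_real_))
  ct <- suppressWarnings(
    stats::cor.test(idx, v, method = "spearman", exact = NULL))
  list(slope = slope,
       rho = unname(ct$estimate),
       pValue = ct$p.value)
}
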