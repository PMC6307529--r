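# Independent brute-force oracles, written without reference to the package
# internals: explicit element loops and dense solves only.

# two-stage normalised diffusion decomposition, naive loops
bruteDiffusion <- function(A, nEig = ncol(A)) {
  n <- nrow(A)
  norm2 <- function(M) {
    j <- numeric(n)
    for (i in seq_len(n)) j[i] <- sum(M[i, ])
    out <- matrix(0, n, n)
    for (i in seq_len(n)) for (k in seq_len(n))
      out[i, k] <- M[i, k] / (sqrt(j[i]) * sqrt(j[k]))
    list(m = out, j = j)
  }
  s1 <- norm2(A)
  W1 <- s1$m %*% s1$m
  s2 <- norm2(W1)
  W2 <- s2$m %*% s2$m
  e <- eigen(W2, symmetric = TRUE)
  ord <- order(e$values, decreasing = TRUE)[seq_len(min(nEig, n))]
  clouds <- e$vectors[, ord, drop = FALSE]
  for (k in seq_along(ord)) clouds[, k] <- clouds[, k] / sqrt(s2$j)
  list(eigenvalues = e$values[ord], pointClouds = clouds, j2 = s2$j)
}

# plug-in MI in bits via cut()/table(), a separate binning path
bruteMI <- function(x, y, nBins) {
  cutEq <- function(v) {
    br <- seq(min(v), max(v), length.out = nBins + 1L)
    br[1L] <- br[1L] - 1e-9; br[nBins + 1L] <- br[nBins + 1L] + 1e-9
    cut(v, br)
  }
  tb <- table(cutEq(x), cutEq(y))
  p <- tb / sum(tb)
  px <- rowSums(p); py <- colSums(p)
  tot <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0)
      tot <- tot + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  as.numeric(tot)
}

# max absolute column-wise difference allowing sign flips
maxColDiffUpToSign <- function(a, b) {
  stopifnot(dim(a) == dim(b))
  max(vapply(seq_len(ncol(a)), function(k)
    min(max(abs(a[, k] - b[, k])), max(abs(a[, k] + b[, k]))), 0))
}

# random valid affinity kernel from squared distances of random points
randomKernel <- function(n, d = 3L, kE = 10) {
  pts <- matrix(stats::rnorm(n * d, sd = 4), n, d)
  dd <- as.matrix(stats::dist(pts))^2
  affinityKernel(dd, kE)
}

# small deterministic multichannel test recording
sineRecording <- function(nCh = 2L, fs = 200, durS = 10, freqs = c(10, 17)) {
  tt <- (seq_len(fs * durS) - 1L) / fs
  data <- t(vapply(seq_len(nCh), function(ch)
    sin(2 * pi * freqs[((ch - 1L) %% length(freqs)) + 1L] * tt), tt))
  EEGRecording(data, fs)
}

# three-subject cohort with hand-computable statistics
workedCohort <- function() {
  list(
    PVSMarkerTable("A", "TBI", 40, "M",
                   hemisphere = c("right", "right", "right", "left", "left"),
                   caliberMm = c(1.0, 1.2, 1.4, 1.0, 1.1)),
    PVSMarkerTable("B", "TBI", 30, "F",
                   hemisphere = c("right", "right", "left", "left"),
                   caliberMm = c(2.0, 2.2, 2.0, 2.4)),
    PVSMarkerTable("C", "control", 25, "M",
                   hemisphere = c("right", "left"),
                   caliberMm = c(1.5, 1.5)))
}
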