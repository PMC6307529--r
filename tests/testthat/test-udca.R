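test_that("segmentation counts 50%-overlapping windows and flattens rows", {
  rec <- EEGRecording(matrix(seq_len(2000), nrow = 2), fs = 200)
  seg <- segmentRecording(rec, 200)
  expect_equal(nSegments(seg), 9)            # (1000 - 200)/100 + 1
  expect_equal(nSegments(segmentRecording(
    EEGRecording(matrix(1:500, 1), 100), 500)), 1)
  expect_error(segmentRecording(
    EEGRecording(matrix(1:150, 1), 100), 200), "windowSize")
  expect_error(segmentRecording(rec, 201), "even")
  # channel-major flattening: channel 1's samples first
  expect_equal(seg@features[1, 1:200], rec@data[1, 1:200])
  expect_equal(seg@features[1, 201:400], rec@data[2, 1:200])
  # consecutive segments share exactly half a window
  expect_equal(seg@segments[[1]][, 101:200], seg@segments[[2]][, 1:100])
})

test_that("cross-correlation QC separates copied from independent channels", {
  set.seed(51)
  x <- rnorm(5120)
  recSame <- EEGRecording(rbind(x, x + 0), fs = 200)
  qcSame <- qcCrossCorrelation(segmentRecording(recSame, 512), maxLag = 32)
  expect_equal(qcSame$maxAbsCC, 1)

  recInd <- EEGRecording(rbind(rnorm(5120), rnorm(5120)), fs = 200)
  qcInd <- qcCrossCorrelation(segmentRecording(recInd, 512), maxLag = 32)
  expect_lt(qcInd$maxAbsCC, 0.3)
  expect_error(qcCrossCorrelation(segmentRecording(recInd, 512),
                                  maxLag = 512), "maxLag")
})

# segment set with two constant segments differing by (3, 4) per channel,
# with pseudo-inverse covariances pinned to the identity
constDiffSegments <- function(scale = 1) {
  s1 <- rbind(rep(0, 10), rep(0, 10))
  s2 <- rbind(rep(3 * scale, 10), rep(4 * scale, 10))
  new("SegmentSet", segments = list(s1, s2),
      features = rbind(as.vector(t(s1)), as.vector(t(s2))),
      covariances = list(diag(2), diag(2)),
      invCovariances = list(diag(2), diag(2)),
      windowSize = 10L, fs = 10, startTimesS = c(0, 0.5),
      channelLabels = c("C1", "C2"))
}

test_that("the Mahalanobis quadratic form matches hand evaluation", {
  expect_equal(mahalanobisMetric(constDiffSegments()), 25)      # 3^2 + 4^2
  # homogeneity: scaling the signal by c scales d by c^2
  expect_equal(mahalanobisMetric(constDiffSegments(3)), 9 * 25)
  # a 100-sample-periodic signal makes every segment identical: distance 0
  rec <- sineRecording(nCh = 2, durS = 4)
  block <- rec@data[, 1:100]
  rec@data <- cbind(block, block, block, block)
  seg <- segmentCovariances(segmentRecording(rec, 200))
  d <- mahalanobisMetric(seg)
  expect_equal(d, rep(0, 2), tolerance = 1e-12)
})

test_that("flat segments yield zero pseudo-inverses with a warning", {
  rec <- EEGRecording(matrix(1, 2, 400), fs = 100)
  expect_warning(seg <- segmentCovariances(segmentRecording(rec, 200)),
                 "zero-variance")
  expect_true(all(vapply(seg@invCovariances, function(m) all(m == 0), TRUE)))
  expect_equal(mahalanobisMetric(seg), rep(0, 2))
})

test_that("the affinity kernel follows exp(-d/(4 kE))", {
  expect_equal(affinityKernel(0, 10), 1)
  expect_equal(affinityKernel(40, 10), exp(-1))
  d <- seq(0, 100, by = 5)
  expect_true(all(diff(affinityKernel(d, 10)) < 0))
  expect_error(affinityKernel(-1, 10), "negative")
  expect_error(affinityKernel(1, 0), "positive")
})

test_that("decomposition matches closed forms on structured kernels", {
  # equidistant 3-point kernel a + b J: eigenvalue 1 simple, rest equal
  A <- matrix(0.4, 3, 3); diag(A) <- 1
  dec <- diffusionDecomposition(A, 3)
  expect_equal(dec$eigenvalues[1], 1, tolerance = 1e-10)
  expect_equal(dec$eigenvalues[2], dec$eigenvalues[3], tolerance = 1e-10)
  expect_lt(dec$eigenvalues[2], 1)

  # 2x2 kernel against a dense brute-force solve
  A2 <- matrix(c(1, 0.3, 0.3, 1), 2)
  dec2 <- diffusionDecomposition(A2, 2)
  br <- bruteDiffusion(A2, 2)
  expect_equal(dec2$eigenvalues, br$eigenvalues, tolerance = 1e-10)
  expect_error(diffusionDecomposition(matrix(c(1, 0.2, 0.8, 1), 2), 2),
               "symmetric")
  expect_error(diffusionDecomposition(matrix(1, 2, 3), 2), "square")
})

test_that("decomposition equals the brute-force oracle on small kernels", {
  set.seed(61)
  for (n in c(5, 8, 12)) {
    A <- randomKernel(n)
    dec <- diffusionDecomposition(A, n)
    br <- bruteDiffusion(A, n)
    expect_equal(dec$eigenvalues, br$eigenvalues, tolerance = 1e-8)
    expect_lt(maxColDiffUpToSign(dec$pointClouds, br$pointClouds), 1e-8)
  }
})

test_that("the normalised operator has a unit leading eigenpair and PSD
           spectrum", {
  set.seed(62)
  for (i in 1:10) {
    A <- randomKernel(sample(6:20, 1))
    dec <- diffusionDecomposition(A, ncol(A))
    expect_equal(dec$eigenvalues[1], 1, tolerance = 1e-8)
    expect_true(all(dec$eigenvalues >= -1e-10))
    expect_true(all(dec$eigenvalues <= 1 + 1e-8))
    lead <- dec$pointClouds[, 1]
    expect_lt(diff(range(lead)) / max(abs(lead)), 1e-6)
  }
})

test_that("Nystrom extension is exact for in-sample and duplicated points", {
  set.seed(63)
  A <- randomKernel(10)
  dec <- diffusionDecomposition(A, 6)
  ext <- nystromExtension(A, dec)
  for (k in seq_len(ncol(ext$psi))) {
    rel <- max(abs(ext$psi[, k] - dec$pointClouds[, k])) /
      max(abs(dec$pointClouds[, k]))
    expect_lt(rel, 1e-6)
  }
  # a held-out point identical to training point 4
  ext4 <- nystromExtension(A[4, , drop = FALSE], dec)
  expect_equal(as.vector(ext4$psi), dec$pointClouds[4, 1:6],
               tolerance = 1e-6)
  expect_error(nystromExtension(A[4, , drop = FALSE], dec, nCoords = 7),
               "more extended coordinates")
})

test_that("extension of a between-cluster midpoint stays inside the
           cluster hull", {
  # two well-separated clusters in feature space
  set.seed(64)
  pts <- rbind(matrix(rnorm(10, 0, 0.1), 5), matrix(rnorm(10, 30, 0.1), 5))
  d2 <- as.matrix(dist(pts))^2
  A <- affinityKernel(d2, kE = 10)
  dec <- diffusionDecomposition(A, 4)
  mid <- colMeans(pts[c(1, 6), ])
  dm <- colSums((t(pts) - mid)^2)
  ext <- nystromExtension(affinityKernel(matrix(dm, 1), 10), dec,
                          nCoords = 2)
  rng <- range(dec$pointClouds[, 2])
  pad <- 0.05 * diff(rng)
  expect_gte(ext$psi[1, 2], rng[1] - pad)
  expect_lte(ext$psi[1, 2], rng[2] + pad)
})

test_that("embedding enumeration excludes the constant eigenvector", {
  pc <- matrix(rnorm(40), 10, 4)
  sel <- selectEmbedding(pc)
  expect_equal(nrow(sel$triples), 1)
  expect_equal(sel$triple, c(2L, 3L, 4L))

  pc7 <- matrix(rnorm(70), 10, 7)
  expect_equal(nrow(selectEmbedding(pc7)$triples), 20)   # C(6, 3)
  expect_true(all(selectEmbedding(pc7)$triples >= 2))
  expect_error(selectEmbedding(pc[, 1:3]), "at least 4")

  # a coincident-point triple is never selected over one with spread
  pcz <- cbind(1, matrix(0, 10, 3), matrix(rnorm(30), 10, 3))
  expect_equal(selectEmbedding(pcz)$triple, c(5L, 6L, 7L))
})

test_that("outlier rules flag by robust distance or exact count", {
  same <- matrix(1, 10, 3)
  expect_false(any(outlierScores(same, "mad", 3)$flags))

  coords <- rbind(matrix(0, 99, 3), c(10, 0, 0))
  om <- outlierScores(coords, "mad", 3)
  expect_identical(which(om$flags), 100L)

  set.seed(65)
  oq <- outlierScores(matrix(rnorm(300), 100, 3), "quantile", 0.05)
  expect_equal(sum(oq$flags), 5)
  expect_error(outlierScores(coords, "mad", 0), "positive")
})

test_that("the full pipeline is deterministic", {
  sim <- genEEG(eegSimConfig(nChannels = 3, durationS = 20, seed = 71))
  r1 <- runUDCA(sim$recording, udcaConfig(windowSize = 200))
  r2 <- runUDCA(sim$recording, udcaConfig(windowSize = 200))
  expect_identical(r1@eigenvalues, r2@eigenvalues)
  expect_identical(outlierFlags(r1), outlierFlags(r2))
  expect_identical(r1@selectedTriple, r2@selectedTriple)
})

test_that("channel order does not affect the embedding", {
  sim <- genEEG(eegSimConfig(nChannels = 3, durationS = 20, seed = 72))
  rec <- sim$recording
  perm <- EEGRecording(rec@data[c(3, 1, 2), ], samplingRate(rec),
                       channelLabels(rec)[c(3, 1, 2)])
  cfg <- udcaConfig(windowSize = 200)
  r1 <- runUDCA(rec, cfg)
  r2 <- runUDCA(perm, cfg)
  expect_equal(r1@distances, r2@distances, tolerance = 1e-10)
  expect_equal(r1@kernel, r2@kernel, tolerance = 1e-10)
  expect_equal(r1@eigenvalues, r2@eigenvalues, tolerance = 1e-10)
  expect_identical(outlierFlags(r1), outlierFlags(r2))
})

test_that("time reversal reverses the window order of outlier flags", {
  sim <- genEEG(eegSimConfig(nChannels = 3, durationS = 20, seed = 73))
  rec <- sim$recording                       # 4000 samples: exact grid fit
  rev <- EEGRecording(rec@data[, ncol(rec@data):1], samplingRate(rec),
                      channelLabels(rec))
  cfg <- udcaConfig(windowSize = 200)
  r1 <- runUDCA(rec, cfg)
  r2 <- runUDCA(rev, cfg)
  expect_identical(outlierFlags(r2), base::rev(outlierFlags(r1)))
})

test_that("spike-bearing records produce dominant outliers; structureless
           records do not", {
  simS <- genEEG(eegSimConfig(nChannels = 3, durationS = 60, seed = 74,
                              spikeRatePerMin = 6))
  simN <- genEEG(eegSimConfig(nChannels = 3, durationS = 60, seed = 74,
                              spikeRatePerMin = 0))
  cfg <- udcaConfig(windowSize = 400)
  domS <- with(list(r = runUDCA(simS$recording, cfg)),
               max(r@outlierScores) / median(r@outlierScores))
  domN <- with(list(r = runUDCA(simN$recording, cfg)),
               max(r@outlierScores) / median(r@outlierScores))
  expect_gt(domS, 2 * domN)
})

test_that("a too-short recording fails with the stage named", {
  rec <- EEGRecording(matrix(rnorm(2 * 300), 2), fs = 100)
  expect_error(runUDCA(rec, udcaConfig(windowSize = 200)), "udca")
})
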