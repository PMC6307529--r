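test_that("EDF write-then-read round-trips shape, labels, fs and values", {
  sim <- genEEG(eegSimConfig(nChannels = 5, durationS = 4, seed = 11))
  rec <- sim$recording
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  rec2 <- readRecording(f)
  expect_identical(dim(signalData(rec2)), dim(signalData(rec)))
  expect_identical(channelLabels(rec2), channelLabels(rec))
  expect_equal(samplingRate(rec2), samplingRate(rec))
  # 16-bit quantization bound: half a digital step per channel
  step <- apply(rec@data, 1, function(r) diff(range(r))) / 65535
  err <- apply(abs(rec@data - rec2@data), 1, max)
  expect_true(all(err <= step * 0.51 + 1e-12))
})

test_that("an independent EDF reader agrees with the writer", {
  # python-mne reads our EDF; channel means must agree (mne reports volts)
  rec <- sineRecording(nCh = 3, durS = 2)
  rec@data <- rec@data * 50 + 7  # nonzero mean, tens of microvolts
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  script <- paste0(
    "import mne, sys; ",
    "raw = mne.io.read_raw_edf('", f, "', preload=True, verbose='ERROR'); ",
    "print(','.join('%.9g' % (d.mean()*1e6) for d in raw.get_data()))")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  vals <- as.numeric(strsplit(out[length(out)], ",")[[1]])
  expect_equal(vals, unname(rowMeans(rec@data)), tolerance = 1e-3)
})

test_that("csv_matrix dialect round-trips and validates", {
  rec <- EEGRecording(matrix(seq_len(10), nrow = 1), fs = 200,
                      channelLabels = "Cz")
  f <- tempfile(fileext = ".csv")
  writeCsvMatrix(rec, f)
  rec2 <- readRecording(f, format = "csv_matrix")
  expect_equal(nSamples(rec2), 10)
  expect_equal(signalData(rec2), signalData(rec))
  expect_equal(samplingRate(rec2), 200)

  # fs side-car is mandatory
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("C1", "1,2,3"), f2)
  expect_error(readRecording(f2, format = "csv_matrix"), "side-car")

  # non-finite samples are a data-integrity error naming the channel
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("C1,C2", "1,2,3", "4,NaN,6"), f3)
  jsonlite::write_json(list(fs = 100), paste0(f3, ".json"),
                       auto_unbox = TRUE)
  expect_error(readRecording(f3, format = "csv_matrix"), "C2")
})

test_that("EDF loader rejects unusable calibration and truncated data", {
  rec <- sineRecording(nCh = 2, durS = 1)
  f <- tempfile(fileext = ".edf")
  writeEDF(rec, f)
  # corrupt the physical-minimum field of channel 2 (field-major layout:
  # 256 header + 2*16 labels + 2*80 transducer + 2*8 dim + second 8-char slot)
  raw <- readBin(f, "raw", file.size(f))
  off <- 256 + 2 * 16 + 2 * 80 + 2 * 8 + 8
  raw[(off + 1):(off + 8)] <- charToRaw(sprintf("%-8s", "nan"))
  f2 <- tempfile(fileext = ".edf")
  writeBin(raw, f2)
  expect_error(readRecording(f2), "C2")
  expect_error(readRecording(tempfile(fileext = ".edf")), "cannot read")
  expect_error(writeEDF(EEGRecording(matrix(c(1, NaN), 1), 10), tempfile()),
               "non-finite")
})

test_that("slicing respects half-open second intervals and channel order", {
  rec <- EEGRecording(matrix(rnorm(3 * 12000), 3), fs = 200,
                      channelLabels = c("C1", "C2", "C3"))
  expect_equal(signalData(sliceRecording(rec, 0, 60)), signalData(rec))
  sl <- sliceRecording(rec, 10, 40)
  expect_equal(nSamples(sl), 6000)          # (40 - 10) * 200
  expect_equal(startTime(sl), 10)
  sl2 <- sliceRecording(rec, 0, 10, channels = c("C3", "C1"))
  expect_identical(channelLabels(sl2), c("C3", "C1"))
  expect_equal(sl2@data[1, ], rec@data[3, 1:2000])
  expect_error(sliceRecording(rec, 5, 5), "out of range")
  expect_error(sliceRecording(rec, 0, 10, channels = character()), "empty")
  expect_error(sliceRecording(rec, 0, 10, channels = "Cz"), "unknown")
})

test_that("slicing composes associatively", {
  rec <- EEGRecording(matrix(rnorm(8000), 2), fs = 100)  # 40 s
  a <- sliceRecording(sliceRecording(rec, 5, 30), 10, 20)
  b <- sliceRecording(rec, 10, 20)
  expect_equal(signalData(a), signalData(b))
  expect_equal(startTime(a), startTime(b))
})

test_that("PVS loader drops out-of-range calibers with a report", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,hemisphere,caliber_mm",
               "s1,TBI,40,M,right,0.4",
               "s1,TBI,40,M,right,0.6",
               "s1,TBI,40,M,left,2.9",
               "s1,TBI,40,M,left,3.1"), f)
  tab <- suppressMessages(readPvsTable(f))
  expect_equal(nrow(pvsMarkers(tab)), 2)
  expect_equal(attr(tab, "dropped"), 2)
  expect_equal(unname(pvsCounts(tab)), c(1L, 1L))
})

test_that("PVS loader validates structure and metadata", {
  empty <- tempfile(fileext = ".csv")
  writeLines("subject_id,group,age,sex,hemisphere,caliber_mm", empty)
  expect_error(readPvsTable(empty), "no marker rows")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,hemisphere,caliber_mm",
               "s1,TBI,40,M,right,1.0",
               "s1,TBI,40,M,middle,1.0"), bad)
  expect_error(readPvsTable(bad), "hemisphere label 'middle' at data row 2")

  meta <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,hemisphere,caliber_mm",
               "s1,TBI,40,M,right,1.0",
               "s1,TBI,41,M,left,1.0"), meta)
  expect_error(readPvsTable(meta), "inconsistent metadata")
})

test_that("a 77-marker table keeps all in-range markers", {
  f <- tempfile(fileext = ".csv")
  set.seed(5)
  writeLines(c("subject_id,group,age,sex,hemisphere,caliber_mm",
               sprintf("s1,TBI,40,M,%s,%.2f",
                       sample(c("right", "left"), 77, replace = TRUE),
                       runif(77, 0.5, 2.9))), f)
  expect_equal(nrow(pvsMarkers(readPvsTable(f))), 77)
})

test_that("PVS cohort write-then-read preserves every subject", {
  cohort <- genPvsCohort(pvsSimConfig(nTbi = 3, nControl = 2, seed = 2))
  f <- tempfile(fileext = ".csv")
  writePvsCohort(cohort, f)
  back <- readPvsCohort(f)
  expect_length(back, 5)
  expect_identical(vapply(back, subjectId, ""),
                   vapply(cohort, subjectId, ""))
  expect_equal(pvsMarkers(back[[1]])$caliber_mm,
               pvsMarkers(cohort[[1]])$caliber_mm, tolerance = 1e-6)
})
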