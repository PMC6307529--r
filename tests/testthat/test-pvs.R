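test_that("hemispheric ratios cover the boundary cases", {
  hr <- hemisphericRatios(60, 40)
  expect_equal(hr$hrMajor, 0.6)
  expect_equal(hr$hrMinor, 0.4)
  expect_equal(hr$minorSide, "left")

  tie <- hemisphericRatios(50, 50)
  expect_identical(tie$hrRight, 0.5)
  expect_identical(tie$hrLeft, 0.5)
  expect_identical(tie$minorSide, "tie")

  onesided <- hemisphericRatios(10, 0)
  expect_identical(onesided$hrMajor, 1)
  expect_identical(onesided$hrMinor, 0)
  expect_error(hemisphericRatios(0, 0), "zero total")
})

test_that("the asymmetry index is the ratio difference", {
  expect_equal(asymmetryIndex(0.4, 0.6), 0.2, tolerance = 1e-12)
  expect_identical(asymmetryIndex(0.5, 0.5), 0)
  expect_identical(asymmetryIndex(0, 1), 1)
  expect_error(asymmetryIndex(0.6, 0.4), "exceed")
  expect_error(asymmetryIndex(0.3, 0.6), "sum to 1")
})

test_that("asymmetry grading is inclusive at 0.2 and monotone", {
  expect_identical(classifyAsymmetry(0.2), "high")
  expect_identical(classifyAsymmetry(0.0), "low")
  expect_identical(classifyAsymmetry(0.15), "intermediate")
  expect_error(classifyAsymmetry(0.1, 0.1, 0.2), "intermediateThreshold")
  lv <- c(low = 1, intermediate = 2, high = 3)
  grades <- lv[classifyAsymmetry(seq(0, 1, by = 0.01))]
  expect_true(all(diff(grades) >= 0))
})

test_that("AI is invariant to hemisphere swap and count scaling", {
  for (i in 1:20) {
    set.seed(i)
    cnt <- sample(1:200, 2)
    a <- hemisphericRatios(cnt[1], cnt[2])
    b <- hemisphericRatios(cnt[2], cnt[1])
    expect_identical(asymmetryIndex(a$hrMinor, a$hrMajor),
                     asymmetryIndex(b$hrMinor, b$hrMajor))
    k <- sample(2:9, 1)
    sc <- hemisphericRatios(k * cnt[1], k * cnt[2])
    expect_equal(asymmetryIndex(sc$hrMinor, sc$hrMajor),
                 asymmetryIndex(a$hrMinor, a$hrMajor))
  }
})

test_that("caliber statistics handle balance, imbalance and empties", {
  tab <- PVSMarkerTable("s", "TBI", 30, "M",
                        hemisphere = c("right", "right", "left"),
                        caliberMm = c(1.0, 2.0, 1.5))
  cs <- caliberStats(tab)
  expect_equal(cs$cRight, 1.5)
  expect_equal(cs$cLeft, 1.5)
  expect_identical(cs$cDiffAbs, 0)

  # group-level mean calibers used as plain arithmetic inputs
  tab2 <- PVSMarkerTable("s2", "TBI", 30, "M",
                         hemisphere = c("right", "left"),
                         caliberMm = c(1.37, 1.31))
  expect_equal(caliberStats(tab2)$cDiffAbs, 0.06)

  tab3 <- PVSMarkerTable("s3", "TBI", 30, "M",
                         hemisphere = "right", caliberMm = 1.2)
  expect_message(cs3 <- caliberStats(tab3), "undefined")
  expect_true(is.na(cs3$cDiffAbs))
})

test_that("group comparison reduces to the classical t-test", {
  same <- cohortCompare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$pValue, 1)

  sep <- cohortCompare(rnorm(4, 0, 1e-4), rnorm(4, 1, 1e-4))
  expect_lt(sep$pValue, 1e-6)
  expect_error(cohortCompare(1, c(1, 2)), "at least 2")

  # printed-style group summaries give |t| < 1 (no group difference)
  ts <- tTestFromSummary(77, 48, 15, 80, 15, 6)
  expect_lt(abs(ts$t), 1)
  expect_equal(ts$df, 19)
  expect_gt(ts$pValue, 0.05)
})

test_that("Pearson correlation matches hand-computed cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlate(x, 2 * x + 1)$r, 1)
  expect_equal(correlate(x, -x)$r, -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_message(z <- correlate(x, rep(2, 5)), "zero variance")
  expect_true(is.na(z$r))
  expect_error(correlate(x, x[-1]), "equal length")
})

test_that("within-subject caliber test discriminates hemisphere gaps", {
  balanced <- PVSMarkerTable("b", "TBI", 30, "M",
                             hemisphere = rep(c("right", "left"), each = 3),
                             caliberMm = rep(c(1.0, 1.2, 1.4), 2))
  expect_equal(subjectCaliberTest(balanced)$pValue, 1)

  set.seed(77)
  gap <- PVSMarkerTable("g", "TBI", 30, "M",
                        hemisphere = rep(c("right", "left"), each = 10),
                        caliberMm = c(1.0 + abs(rnorm(10, 0, 0.01)),
                                      2.0 + abs(rnorm(10, 0, 0.01))))
  expect_lt(subjectCaliberTest(gap)$pValue, 0.001)

  thin <- PVSMarkerTable("t", "TBI", 30, "M",
                         hemisphere = c("right", "left"),
                         caliberMm = c(1, 2))
  expect_message(res <- subjectCaliberTest(thin), "fewer than 2")
  expect_true(is.na(res$pValue))
})

test_that("a 0.4 mm hemisphere gap is detected in most replicates", {
  set.seed(3)
  hits <- replicate(200, {
    tab <- PVSMarkerTable("p", "TBI", 30, "M",
                          hemisphere = rep(c("right", "left"), each = 20),
                          caliberMm = pmin(pmax(
                            c(rnorm(20, 1.5, 0.2), rnorm(20, 1.1, 0.2)),
                            0.5), 2.99))
    subjectCaliberTest(tab)$pValue < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("the cohort report reproduces a hand-computed 3-subject fixture", {
  rep <- cohortReport(workedCohort())
  s <- rep$subjects
  expect_equal(nrow(s), 3)
  A <- s[s$subject_id == "A", ]
  expect_equal(A$pvs_tot, 5)
  expect_equal(A$hr_major, 0.6)
  expect_equal(A$ai, 0.2)
  expect_identical(A$grade, "high")
  expect_equal(A$c_right, 1.2)
  expect_equal(A$c_left, 1.05)
  expect_equal(A$c_diff_abs, 0.15)

  B <- s[s$subject_id == "B", ]
  expect_equal(B$ai, 0)
  expect_identical(B$grade, "low")
  expect_equal(B$c_diff_abs, 0.1, tolerance = 1e-12)

  g <- rep$groups
  tbi <- g[g$group == "TBI", ]
  expect_equal(tbi$total_mean, 4.5)
  expect_equal(tbi$total_sd, sqrt(0.5))
  expect_equal(tbi$ai_mean, 0.1)
  expect_equal(tbi$n_high, 1)

  # frozen from the direct correlation formula on (0.2,0,0) vs (0.15,0.1,0)
  expect_equal(rep$aiVsCdiff$r, 0.7559289, tolerance = 1e-6)

  # control group has a single subject: group tests are unavailable,
  # per-subject rows still emitted
  expect_null(rep$aiTest)
  expect_equal(sum(s$group == "control"), 1)
})

test_that("an all-balanced cohort reports zero asymmetry everywhere", {
  tabs <- lapply(1:4, function(i)
    PVSMarkerTable(paste0("s", i), if (i <= 2) "TBI" else "control", 30, "M",
                   hemisphere = rep(c("right", "left"), each = 5),
                   caliberMm = rep(1.5, 10)))
  rep <- cohortReport(tabs)
  expect_true(all(rep$subjects$ai == 0))
  expect_true(all(rep$groups$n_high == 0))
  expect_equal(rep$groups$ai_mean, c(0, 0))
})

test_that("marker-free subjects are excluded with a report", {
  tabs <- c(workedCohort(),
            PVSMarkerTable("empty", "control", 20, "F"))
  expect_message(rep <- cohortReport(tabs), "excluded")
  expect_identical(rep$excluded, "empty")
  expect_equal(nrow(rep$subjects), 3)
})
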