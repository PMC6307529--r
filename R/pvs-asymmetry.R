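#' Hemispheric PVS ratios
#'
#' Each hemisphere's share of the subject's total PVS count:
#' \eqn{HR_h = PVS_h / PVS_{tot}}. The smaller and larger shares are returned
#' as \code{hrMinor}/\code{hrMajor}; an exact tie gives both equal to 0.5.
#'
#' @param pvsRight,pvsLeft non-negative hemisphere counts, total >= 1.
#' @return named list: \code{hrRight}, \code{hrLeft}, \code{hrMinor},
#'   \code{hrMajor}, and \code{minorSide} (\code{"right"}, \code{"left"} or
#'   \code{"tie"}).
#' @examples
#' hemisphericRatios(60, 40)  # hrMajor 0.6; AI will be 0.2
#' @export
hemisphericRatios <- function(pvsRight, pvsLeft) {
  if (pvsRight < 0 || pvsLeft < 0)
    stop("counts must be non-negative")
  tot <- pvsRight + pvsLeft
  if (tot < 1)
    stop("undefined subject: zero total PVS count")
  hrR <- pvsRight / tot
  hrL <- pvsLeft / tot
  list(hrRight = hrR, hrLeft = hrL,
       hrMinor = min(hrR, hrL), hrMajor = max(hrR, hrL),
       minorSide = if (hrR < hrL) "right" else if (hrL < hrR) "left" else "tie")
}

#' Asymmetry index
#'
#' \eqn{AI = HR_{major} - HR_{minor}}, in [0, 1]. Larger values mean a more
#' asymmetric hemispheric distribution of PVSs; AI = 0.2 corresponds to one
#' hemisphere holding 60\% of all PVSs.
#'
#' @param hrMinor,hrMajor hemispheric ratios with \code{hrMinor <= hrMajor}
#'   and \code{hrMinor + hrMajor == 1}.
#' @return the asymmetry index (scalar).
#' @export
asymmetryIndex <- function(hrMinor, hrMajor) {
  if (hrMinor > hrMajor)
    stop("hrMinor must not exceed hrMajor")
  if (abs(hrMinor + hrMajor - 1) > 1e-9)
    stop("hemispheric ratios must sum to 1")
  hrMajor - hrMinor
}

#' Grade an asymmetry index
#'
#' AI at or above the high threshold (default 0.2, i.e. one hemisphere with
#' more than 60\% of PVSs) is graded \code{"high"}; between the intermediate
#' and high thresholds, \code{"intermediate"}; otherwise \code{"low"}. The
#' intermediate band default (0.1) is a package convention; only the high
#' threshold has an established definition.
#'
#' @param ai asymmetry index in [0, 1] (vectorised).
#' @param highThreshold default 0.2.
#' @param intermediateThreshold default 0.1; must be below
#'   \code{highThreshold}.
#' @return character vector of grades.
#' @export
classifyAsymmetry <- function(ai, highThreshold = 0.2,
                              intermediateThreshold = 0.1) {
  if (!(intermediateThreshold > 0 && intermediateThreshold < highThreshold))
    stop("need 0 < intermediateThreshold < highThreshold")
  if (any(ai < 0 | ai > 1)) stop("ai must lie in [0, 1]")
  ifelse(ai >= highThreshold, "high",
         ifelse(ai >= intermediateThreshold, "intermediate", "low"))
}

#' Per-hemisphere caliber statistics of one subject
#'
#' Mean PVS caliber in each hemisphere and the absolute difference
#' \eqn{|C_{diff}| = |C_{right} - C_{left}|}. A hemisphere without markers
#' leaves the dependent fields \code{NA} with a message.
#'
#' @param table a \code{\linkS4class{PVSMarkerTable}}.
#' @return list: \code{cRight}, \code{cLeft}, \code{cDiffAbs},
#'   \code{calibersRight}, \code{calibersLeft}.
#' @export
caliberStats <- function(table) {
  stopifnot(is(table, "PVSMarkerTable"))
  m <- table@markers
  r <- m$caliber_mm[m$hemisphere == "right"]
  l <- m$caliber_mm[m$hemisphere == "left"]
  cR <- if (length(r)) mean(r) else NA_real_
  cL <- if (length(l)) mean(l) else NA_real_
  if (is.na(cR) || is.na(cL))
    message("caliberStats: subject ", table@subjectId,
            " lacks markers in one hemisphere; |C_diff| undefined")
  list(cRight = cR, cLeft = cL,
       cDiffAbs = if (is.na(cR) || is.na(cL)) NA_real_ else abs(cR - cL),
       calibersRight = r, calibersLeft = l)
}

#' Two-group comparison of a subject-level metric
#'
#' Classical Student's t-test (equal variance, two-sided) between two groups
#' of subject metrics, with group means and SDs. A Welch test is available
#' behind \code{welch = TRUE}.
#'
#' @param groupA,groupB numeric vectors, each of length >= 2.
#' @param welch use the unequal-variance (Welch) form; default \code{FALSE}.
#' @return list: \code{t}, \code{pValue}, \code{meanA}, \code{meanB},
#'   \code{sdA}, \code{sdB}, \code{summary} (means +/- SD, formatted).
#' @export
cohortCompare <- function(groupA, groupB, welch = FALSE) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 subjects")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    eq <- mean(groupA) == mean(groupB)
    tt <- list(statistic = c(t = if (eq) 0 else Inf),
               p.value = if (eq) 1 else 0)
  } else
  tt <- stats::t.test(groupA, groupB, var.equal = !welch)
  list(t = unname(tt$statistic), pValue = tt$p.value,
       meanA = mean(groupA), meanB = mean(groupB),
       sdA = stats::sd(groupA), sdB = stats::sd(groupB),
       summary = sprintf("%.2f ± %.2f vs %.2f ± %.2f",
                         mean(groupA), stats::sd(groupA),
                         mean(groupB), stats::sd(groupB)))
}

#' Equal-variance t-test from summary statistics
#'
#' Two-sided Student's t computed from printed group summaries (mean, SD, n)
#' rather than raw values.
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with \code{t}, \code{df}, \code{pValue}.
#' @examples
#' tTestFromSummary(77, 48, 15, 80, 15, 6)
#' @export
tTestFromSummary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, pValue = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation between two subject metrics
#'
#' @param x,y equal-length numeric vectors, length >= 3, finite.
#' @return list with \code{r} and two-sided t-based \code{pValue}; zero
#'   variance in either vector gives \code{NA} values with a message.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 subjects")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("correlate: zero variance; correlation undefined")
    return(list(r = NA_real_, pValue = NA_real_))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), pValue = ct$p.value)
}

#' Within-subject caliber test between hemispheres
#'
#' Two-sample t-test between a subject's right- and left-hemisphere caliber
#' samples, asking whether that subject's PVSs differ in caliber by side.
#'
#' @param table a \code{\linkS4class{PVSMarkerTable}} with >= 2 markers per
#'   hemisphere.
#' @param welch Welch form; default \code{FALSE} (Student).
#' @return list with \code{t} and \code{pValue}; insufficient markers give
#'   \code{NA} values with a message.
#' @export
subjectCaliberTest <- function(table, welch = FALSE) {
  cs <- caliberStats(table)
  if (length(cs$calibersRight) < 2L || length(cs$calibersLeft) < 2L) {
    message("subjectCaliberTest: subject ", table@subjectId,
            " has fewer than 2 markers in a hemisphere; test undefined")
    return(list(t = NA_real_, pValue = NA_real_))
  }
  if (stats::sd(cs$calibersRight) == 0 && stats::sd(cs$calibersLeft) == 0) {
    eq <- cs$cRight == cs$cLeft
    return(list(t = if (eq) 0 else Inf, pValue = if (eq) 1 else 0))
  }
  tt <- stats::t.test(cs$calibersRight, cs$calibersLeft, var.equal = !welch)
  list(t = unname(tt$statistic), pValue = tt$p.value)
}

#' Per-subject asymmetry summary
#'
#' Derives the full per-subject row: hemisphere counts, hemispheric ratios,
#' asymmetry index and grade, mean calibers and \eqn{|C_{diff}|}.
#'
#' @param table a \code{\linkS4class{PVSMarkerTable}}.
#' @param highThreshold,intermediateThreshold grading thresholds, see
#'   \code{\link{classifyAsymmetry}}.
#' @return one-row data.frame with columns \code{subject_id}, \code{group},
#'   \code{age}, \code{sex}, \code{pvs_right}, \code{pvs_left},
#'   \code{pvs_tot}, \code{hr_right}, \code{hr_left}, \code{hr_minor},
#'   \code{hr_major}, \code{minor_side}, \code{ai}, \code{grade},
#'   \code{c_right}, \code{c_left}, \code{c_diff_abs}.
#' @export
subjectAsymmetry <- function(table, highThreshold = 0.2,
                             intermediateThreshold = 0.1) {
  stopifnot(is(table, "PVSMarkerTable"))
  cnt <- pvsCounts(table)
  hr <- hemisphericRatios(cnt["right"], cnt["left"])
  # count-exact form of hrMajor - hrMinor: keeps the 0.2 grading boundary
  # free of floating-point subtraction error
  ai <- abs(cnt[["right"]] - cnt[["left"]]) / sum(cnt)
  cs <- suppressMessages(caliberStats(table))
  data.frame(subject_id = table@subjectId, group = table@group,
             age = table@ageYears, sex = table@sex,
             pvs_right = unname(cnt["right"]), pvs_left = unname(cnt["left"]),
             pvs_tot = unname(sum(cnt)),
             hr_right = hr$hrRight, hr_left = hr$hrLeft,
             hr_minor = hr$hrMinor, hr_major = hr$hrMajor,
             minor_side = hr$minorSide, ai = ai,
             grade = classifyAsymmetry(ai, highThreshold,
                                       intermediateThreshold),
             c_right = cs$cRight, c_left = cs$cLeft,
             c_diff_abs = cs$cDiffAbs,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cohort-level PVS report
#'
#' Recomputes on any cohort the full battery of subject- and group-level PVS
#' statistics: per-subject asymmetry rows; group mean +/- SD of total
#' counts; hemispheric-ratio ranges and group means of the minor/major
#' ratios; group mean AI with the between-group Student's t-test; group mean
#' caliber with its t-test; the AI vs \eqn{|C_{diff}|} Pearson correlation;
#' the age vs total-count correlation; high-asymmetry subject counts; and
#' within-subject caliber tests. Subjects with zero in-range markers are
#' excluded with a report. Group tests require >= 2 subjects per group and
#' are \code{NA} otherwise.
#'
#' @param tables list of \code{\linkS4class{PVSMarkerTable}} (both groups).
#' @param highThreshold,intermediateThreshold grading thresholds.
#' @return list with elements \code{subjects} (data.frame),
#'   \code{excluded} (subject ids), \code{groups} (per-group summary
#'   data.frame), \code{aiTest}, \code{caliberTest}, \code{totalsTest}
#'   (each a \code{\link{cohortCompare}} result or NULL),
#'   \code{aiVsCdiff}, \code{ageVsTotal} (\code{\link{correlate}} results),
#'   and \code{caliberBySubject} (within-subject test results).
#' @export
cohortReport <- function(tables, highThreshold = 0.2,
                         intermediateThreshold = 0.1) {
  if (is(tables, "PVSMarkerTable")) tables <- list(tables)
  empty <- vapply(tables, function(tb) nrow(tb@markers) == 0L, TRUE)
  excluded <- vapply(tables[empty], subjectId, "")
  if (length(excluded))
    message("cohortReport: excluded subject(s) without markers: ",
            paste(excluded, collapse = ", "))
  tables <- tables[!empty]
  if (length(tables) == 0L) stop("no subjects with markers")
  subjects <- do.call(rbind, lapply(tables, subjectAsymmetry,
                                    highThreshold = highThreshold,
                                    intermediateThreshold = intermediateThreshold))
  # order of appearance, not locale collation, for reproducible group order
  grp <- split(subjects, factor(subjects$group, unique(subjects$group)))
  groups <- do.call(rbind, lapply(names(grp), function(g) {
    s <- grp[[g]]
    data.frame(group = g, n = nrow(s),
               total_mean = mean(s$pvs_tot), total_sd = stats::sd(s$pvs_tot),
               hr_min = min(s$hr_minor), hr_max = max(s$hr_major),
               hr_minor_mean = mean(s$hr_minor),
               hr_major_mean = mean(s$hr_major),
               ai_mean = mean(s$ai), ai_sd = stats::sd(s$ai),
               caliber_mean = mean(c(s$c_right, s$c_left), na.rm = TRUE),
               n_high = sum(s$grade == "high"),
               n_intermediate = sum(s$grade == "intermediate"),
               stringsAsFactors = FALSE)
  }))
  twoGroups <- length(grp) == 2L && all(vapply(grp, nrow, 0L) >= 2L)
  pairTest <- function(col) {
    if (!twoGroups) return(NULL)
    cohortCompare(grp[[1L]][[col]], grp[[2L]][[col]])
  }
  caliberOf <- function(s) rowMeans(cbind(s$c_right, s$c_left), na.rm = TRUE)
  caliberTest <- if (twoGroups)
    cohortCompare(caliberOf(grp[[1L]]), caliberOf(grp[[2L]])) else NULL
  ok <- !is.na(subjects$c_diff_abs)
  aiVsCdiff <- if (sum(ok) >= 3L)
    correlate(subjects$ai[ok], subjects$c_diff_abs[ok]) else NULL
  ageVsTotal <- if (nrow(subjects) >= 3L)
    correlate(subjects$age, subjects$pvs_tot) else NULL
  caliberBySubject <- lapply(tables, function(tb)
    c(list(subject_id = subjectId(tb)),
      suppressMessages(subjectCaliberTest(tb))))
  list(subjects = subjects, excluded = excluded, groups = groups,
       aiTest = pairTest("ai"), totalsTest = pairTest("pvs_tot"),
       caliberTest = caliberTest, aiVsCdiff = aiVsCdiff,
       ageVsTotal = ageVsTotal, caliberBySubject = caliberBySubject)
}
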