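#' Configuration of the synthetic PVS cohort generator
#'
#' Defaults emulate a small TBI-vs-control MRI cohort: 15 TBI and 6 control
#' subjects, around 78 marked PVSs per subject, group-mean asymmetry indices
#' of 0.17 (TBI-like) and 0.04 (control-like), calibers around 1.35 mm with
#' SD 0.24 mm inside the reliable [0.5, 3) mm marking range, and a
#' caliber-asymmetry coupling of 0.5 mm of \eqn{|C_{diff}|} per unit AI
#' applied as a negative offset on the minor side (the hemisphere with
#' fewer PVSs also carries the smaller ones).
#'
#' @param nTbi,nControl group sizes; defaults 15 and 6.
#' @param targetMeanAi named numeric, group-mean AI targets; default
#'   \code{c(TBI = 0.17, control = 0.04)}.
#' @param countScale mean total PVS count per subject; default 78.
#' @param countSd SD of the total count; default 30.
#' @param caliberMeanMm,caliberSdMm caliber distribution in mm; defaults
#'   1.35 and 0.24.
#' @param caliberAsymmetrySlope mm of minor-side mean-caliber deficit per
#'   unit AI; default 0.5.
#' @param aiConcentration Beta concentration of the per-subject AI draw
#'   (mean fixed at the group target); default 20.
#' @param ageRange years, uniform; default \code{c(18, 65)}.
#' @param seed integer seed.
#' @return validated list of class \code{"pvsSimConfig"}.
#' @export
pvsSimConfig <- function(nTbi = 15L, nControl = 6L,
                         targetMeanAi = c(TBI = 0.17, control = 0.04),
                         countScale = 78, countSd = 30,
                         caliberMeanMm = 1.35, caliberSdMm = 0.24,
                         caliberAsymmetrySlope = 0.5,
                         aiConcentration = 20,
                         ageRange = c(18, 65), seed = 1L) {
  if (any(targetMeanAi < 0) || any(targetMeanAi > 1))
    stop("targetMeanAi must lie in [0, 1]")
  if (caliberMeanMm - caliberAsymmetrySlope <= 0.5 || caliberMeanMm >= 3)
    stop("infeasible caliber bounds: offsets would push calibers outside ",
         "[0.5, 3) mm")
  if (countScale <= 0 || countSd < 0) stop("bad count parameters")
  structure(list(nTbi = as.integer(nTbi), nControl = as.integer(nControl),
                 targetMeanAi = targetMeanAi, countScale = countScale,
                 countSd = countSd, caliberMeanMm = caliberMeanMm,
                 caliberSdMm = caliberSdMm,
                 caliberAsymmetrySlope = caliberAsymmetrySlope,
                 aiConcentration = aiConcentration,
                 ageRange = ageRange, seed = as.integer(seed)),
            class = "pvsSimConfig")
}

# truncated-normal caliber draw inside [0.5, 3) by resampling
drawCalibers <- function(k, meanMm, sdMm) {
  out <- stats::rnorm(k, meanMm, sdMm)
  bad <- which(out < 0.5 | out >= 3)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), meanMm, sdMm)
    bad <- bad[out[bad] < 0.5 | out[bad] >= 3]
  }
  out
}

#' Generate a synthetic PVS cohort with ground truth
#'
#' Per subject the total count is drawn around \code{countScale}; the
#' asymmetry index is drawn from a Beta distribution whose mean equals the
#' group target, and the hemisphere split is derived deterministically from
#' it (\code{nMajor = round(total (1 + AI) / 2)}), so the measured group-mean
#' AI converges to the target; per-marker calibers are drawn truncated-normal
#' with the minor side's mean lowered by \code{caliberAsymmetrySlope * AI}.
#' Reproducible from the seed.
#'
#' @param cfg a \code{\link{pvsSimConfig}}.
#' @return list of \code{\linkS4class{PVSMarkerTable}} with attribute
#'   \code{truth}, a data.frame of subject id, group and drawn AI.
#' @examples
#' cohort <- genPvsCohort(pvsSimConfig(seed = 3))
#' mean(cohortReport(cohort)$subjects$ai[1:15])
#' @export
genPvsCohort <- function(cfg) {
  stopifnot(inherits(cfg, "pvsSimConfig"))
  specs <- data.frame(
    group = rep(c("TBI", "control"), c(cfg$nTbi, cfg$nControl)),
    id = c(sprintf("tbi%02d", seq_len(cfg$nTbi)),
           sprintf("ctl%02d", seq_len(cfg$nControl))),
    stringsAsFactors = FALSE)
  set.seed(componentSeed(cfg$seed, "pvs-cohort"))
  tables <- vector("list", nrow(specs))
  truth <- data.frame(subject_id = specs$id, group = specs$group,
                      true_ai = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(specs))) {
    target <- cfg$targetMeanAi[[specs$group[i]]]
    total <- max(10L, round(stats::rnorm(1L, cfg$countScale, cfg$countSd)))
    ai <- if (target > 0)
      stats::rbeta(1L, target * cfg$aiConcentration,
                   (1 - target) * cfg$aiConcentration)
    else 0
    nMajor <- round(total * (1 + ai) / 2)
    nMinor <- total - nMajor
    majorSide <- sample(c("right", "left"), 1L)
    minorSide <- setdiff(c("right", "left"), majorSide)
    calMajor <- drawCalibers(nMajor, cfg$caliberMeanMm, cfg$caliberSdMm)
    calMinor <- drawCalibers(nMinor,
                             cfg$caliberMeanMm - cfg$caliberAsymmetrySlope * ai,
                             cfg$caliberSdMm)
    tables[[i]] <- PVSMarkerTable(
      specs$id[i], specs$group[i],
      ageYears = round(stats::runif(1L, cfg$ageRange[1L], cfg$ageRange[2L])),
      sex = sample(c("M", "F"), 1L),
      hemisphere = rep(c(majorSide, minorSide), c(nMajor, nMinor)),
      caliberMm = c(calMajor, calMinor))
    truth$true_ai[i] <- ai
  }
  attr(tables, "truth") <- truth
  tables
}
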