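#' Construct a per-subject PVS marker table
#'
#' @param subjectId subject identifier.
#' @param group \code{"TBI"} or \code{"control"}.
#' @param ageYears age in years.
#' @param sex \code{"M"} or \code{"F"}.
#' @param hemisphere character vector, \code{"right"}/\code{"left"}, one per
#'   marker.
#' @param caliberMm marker calibers in mm, each in [0.5, 3).
#' @return a \code{\linkS4class{PVSMarkerTable}}.
#' @examples
#' tab <- PVSMarkerTable("s1", "TBI", 34, "M",
#'                       hemisphere = c("right", "right", "left"),
#'                       caliberMm = c(1.2, 0.8, 1.6))
#' pvsCounts(tab)
#' @export
PVSMarkerTable <- function(subjectId, group, ageYears, sex,
                           hemisphere = character(), caliberMm = numeric()) {
  new("PVSMarkerTable", subjectId = as.character(subjectId),
      group = as.character(group), ageYears = as.numeric(ageYears),
      sex = as.character(sex),
      markers = data.frame(hemisphere = as.character(hemisphere),
                           caliber_mm = as.numeric(caliberMm),
                           stringsAsFactors = FALSE))
}

#' @describeIn PVSMarkerTable marker data.frame
#' @param x a \code{PVSMarkerTable}.
#' @export
setMethod("pvsMarkers", "PVSMarkerTable", function(x) x@markers)

#' @describeIn PVSMarkerTable subject identifier
#' @export
setMethod("subjectId", "PVSMarkerTable", function(x) x@subjectId)

#' Hemisphere PVS counts of one subject
#' @param table a \code{\linkS4class{PVSMarkerTable}}.
#' @return named integer vector with elements \code{right}, \code{left}.
#' @export
pvsCounts <- function(table) {
  stopifnot(is(table, "PVSMarkerTable"))
  h <- table@markers$hemisphere
  c(right = sum(h == "right"), left = sum(h == "left"))
}

setMethod("show", "PVSMarkerTable", function(object) {
  cnt <- pvsCounts(object)
  cat("PVSMarkerTable: subject", object@subjectId,
      sprintf("(%s, %s, %.0f y)", object@group, object@sex, object@ageYears),
      "\n  markers:", nrow(object@markers),
      sprintf("(right %d / left %d)\n", cnt["right"], cnt["left"]))
})

parsePvsRows <- function(df, path) {
  need <- c("subject_id", "group", "age", "sex", "hemisphere", "caliber_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("PVS table format error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  hemi <- tolower(trimws(as.character(df$hemisphere)))
  badH <- which(!hemi %in% c("right", "left"))
  if (length(badH))
    stop("PVS table format error in ", path, ": unknown hemisphere label '",
         df$hemisphere[badH[1L]], "' at data row ", badH[1L])
  df$hemisphere <- hemi
  df$caliber_mm <- as.numeric(df$caliber_mm)
  df
}

buildSubjectTable <- function(df, path, permissive) {
  meta <- unique(df[, c("subject_id", "group", "age", "sex")])
  if (nrow(meta) != 1L)
    stop("PVS table format error in ", path, ": inconsistent metadata for ",
         "subject ", df$subject_id[1L])
  inRange <- df$caliber_mm >= 0.5 & df$caliber_mm < 3
  dropped <- sum(!inRange)
  df <- df[inRange, , drop = FALSE]
  if (nrow(df) == 0L && !permissive)
    stop("PVS table error in ", path, ": subject ", meta$subject_id,
         " has no markers in the [0.5, 3) mm range (permissive mode admits ",
         "empty subjects)")
  tab <- PVSMarkerTable(meta$subject_id, meta$group, meta$age, meta$sex,
                        df$hemisphere, df$caliber_mm)
  attr(tab, "dropped") <- dropped
  tab
}

#' Read a PVS marker table
#'
#' Reads a UTF-8 CSV with columns \code{subject_id, group, age, sex,
#' hemisphere, caliber_mm}, one marked PVS per row. Markers with calibers
#' outside the reliable [0.5, 3) mm marking range are dropped and counted in
#' the load report (a message, and the \code{"dropped"} attribute of the
#' result).
#'
#' @param path CSV file path holding exactly one subject.
#' @param permissive if \code{TRUE}, a subject with zero in-range markers is
#'   returned empty instead of raising an error.
#' @return a \code{\linkS4class{PVSMarkerTable}} with attribute
#'   \code{dropped} (count of out-of-range markers).
#' @seealso \code{\link{readPvsCohort}} for multi-subject files.
#' @export
readPvsTable <- function(path, permissive = FALSE) {
  tabs <- readPvsCohort(path, permissive = permissive)
  if (length(tabs) != 1L)
    stop("PVS table format error in ", path, ": expected one subject, found ",
         length(tabs), " (use readPvsCohort)")
  tabs[[1L]]
}

#' Read a multi-subject PVS marker file
#'
#' @inheritParams readPvsTable
#' @param path CSV file path; rows are grouped by \code{subject_id}.
#' @return list of \code{\linkS4class{PVSMarkerTable}}, one per subject, each
#'   carrying a \code{dropped} attribute.
#' @export
readPvsCohort <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop("cannot read PVS table: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    stop("PVS table format error in ", path, ": file holds no marker rows")
  df <- parsePvsRows(df, path)
  tabs <- lapply(split(df, factor(df$subject_id, unique(df$subject_id))),
                 buildSubjectTable, path = path, permissive = permissive)
  dropped <- sum(vapply(tabs, attr, 0, which = "dropped"))
  if (dropped > 0L)
    message("readPvsCohort: dropped ", dropped,
            " marker(s) outside the [0.5, 3) mm caliber range")
  unname(tabs)
}

#' Write PVS marker tables as CSV
#'
#' @param tables a \code{\linkS4class{PVSMarkerTable}} or a list of them.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writePvsCohort <- function(tables, path) {
  if (is(tables, "PVSMarkerTable")) tables <- list(tables)
  rows <- lapply(tables, function(tab) {
    m <- tab@markers
    if (nrow(m) == 0L) return(NULL)
    data.frame(subject_id = tab@subjectId, group = tab@group,
               age = tab@ageYears, sex = tab@sex,
               hemisphere = m$hemisphere, caliber_mm = m$caliber_mm,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
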