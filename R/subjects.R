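#' Build and validate subject metadata records
#'
#' Handedness is derived from the sign of the Edinburgh Handedness Inventory
#' (EHI) score: right-handed (`RH`) for positive scores, left-handed (`LH`)
#' for negative scores. An EHI of exactly 0 (ambidexterity) has no group and
#' is rejected.
#'
#' @param subjectId character vector of unique identifiers.
#' @param ehi integer vector in `[-100, 100]`, nonzero.
#' @param handedness optional character vector (`"LH"`/`"RH"`); if supplied it
#'   is checked for consistency with `sign(ehi)`, otherwise it is derived.
#' @return A data.frame with columns `subject_id`, `handedness`, `ehi`.
#' @examples
#' subjectRecords(c("S1", "S2"), ehi = c(-40, 100))
#' @export
subjectRecords <- function(subjectId, ehi, handedness = NULL) {
  subjectId <- as.character(subjectId)
  ehi <- as.integer(ehi)
  if (anyDuplicated(subjectId)) stop("duplicate subject identifiers")
  if (anyNA(ehi) || any(abs(ehi) > 100L))
    stop("'ehi' must be integers in [-100, 100]")
  if (any(ehi == 0L))
    stop("EHI of 0 (ambidextrous) cannot be assigned to a handedness group")
  derived <- ifelse(ehi > 0L, "RH", "LH")
  if (is.null(handedness)) handedness <- derived
  if (!all(handedness == derived))
    stop("handedness labels inconsistent with EHI sign")
  data.frame(subject_id = subjectId, handedness = handedness, ehi = ehi)
}

#' Read / write the subject metadata TSV
#'
#' Columns: `subject_id`, `handedness`, `ehi`.
#'
#' @param path file path.
#' @return `readSubjectRecords()` returns the validated data.frame.
#' @export
readSubjectRecords <- function(path) {
  df <- readTsv(path)
  need <- c("subject_id", "handedness", "ehi")
  if (!all(need %in% colnames(df)))
    stop("subject file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  subjectRecords(df$subject_id, df$ehi, df$handedness)
}

#' @rdname readSubjectRecords
#' @param subjects data.frame as returned by [subjectRecords()].
#' @export
writeSubjectRecords <- function(subjects, path) {
  writeTsv(subjects[, c("subject_id", "handedness", "ehi")], path)
}
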