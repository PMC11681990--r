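## Positive-element (PE) extraction: from a vertex-level statistical map to
## per-parcel counts of vertices that are positive and at or above the map
## mean, plus hemisphere totals.

#' Compute the PE threshold of a map
#'
#' The PE threshold of one subject x contrast map is the arithmetic mean of
#' its vertex values. With the default basis `"full_map"` the mean is taken
#' over all vertices of both hemispheres, negatives included; with
#' `"nonnegative_map"` it is the mean of the nonnegative values only (the
#' discard-negatives step applied before averaging). Either way a vertex
#' must also be strictly positive to count as a PE, so the effective
#' threshold is `max(0, mean)`.
#'
#' @param map a [VertexScalarMap-class].
#' @param thresholdBasis which values enter the mean.
#' @return The threshold (scalar). With `"nonnegative_map"` and an
#'   all-negative map there is nothing to average; `Inf` is returned so that
#'   no vertex qualifies.
#' @examples
#' m <- vertexScalarMap("S1", "STORY", c(-1, 0.6), c(0.5, 2))
#' computeThreshold(m)  # 0.525
#' @export
computeThreshold <- function(map,
                             thresholdBasis = c("full_map", "nonnegative_map")) {
  stopifnot(is(map, "VertexScalarMap"))
  thresholdBasis <- match.arg(thresholdBasis)
  v <- mapValues(map)
  if (!length(v)) stop("empty map")
  if (thresholdBasis == "full_map") return(mean(v))
  vv <- v[v >= 0]
  if (!length(vv)) return(Inf)
  mean(vv)
}

#' Count positive elements per parcel
#'
#' A vertex is a positive element iff its value is strictly positive and at
#' or above the map's threshold (ties at the threshold count). Counts are
#' aggregated per sided parcel; hemisphere totals and the whole-surface
#' total are appended.
#'
#' @param map a [VertexScalarMap-class].
#' @param parc a [Parcellation-class] covering the same vertex sets.
#' @inheritParams computeThreshold
#' @return Named integer vector: one count per sided parcel label (left
#'   block, then right block), then `total_left`, `total_right`,
#'   `total_surface`.
#' @export
countPositiveElements <- function(map, parc,
                                  thresholdBasis = c("full_map", "nonnegative_map")) {
  stopifnot(is(map, "VertexScalarMap"), is(parc, "Parcellation"))
  if (nVerticesPerHemi(map) != length(parc@assignmentLeft))
    stop("map has ", nVerticesPerHemi(map),
         " vertices per hemisphere but parcellation expects ",
         length(parc@assignmentLeft))
  thr <- computeThreshold(map, thresholdBasis)
  p <- nParcelsPerHemi(parc)
  countSide <- function(values, assignment) {
    pe <- values > 0 & values >= thr
    tabulate(assignment[pe], nbins = p)
  }
  counts <- c(countSide(map@valuesLeft, parc@assignmentLeft),
              countSide(map@valuesRight, parc@assignmentRight))
  names(counts) <- parcelLabels(parc)
  tl <- sum(counts[seq_len(p)])
  tr <- sum(counts[p + seq_len(p)])
  c(counts, total_left = tl, total_right = tr, total_surface = tl + tr)
}

#' Build a PE count table from a cohort of maps
#'
#' @param maps list of [VertexScalarMap-class] objects.
#' @param parc the common [Parcellation-class].
#' @param subjects optional data.frame from [subjectRecords()]; its
#'   `handedness` and `ehi` are joined onto the samples.
#' @inheritParams computeThreshold
#' @return A [PECountTable-class]: sided parcels x (subject, contrast)
#'   samples, assay `counts`.
#' @export
peCountTable <- function(maps, parc, subjects = NULL,
                         thresholdBasis = c("full_map", "nonnegative_map")) {
  thresholdBasis <- match.arg(thresholdBasis)
  stopifnot(length(maps) > 0L)
  p <- nParcelsPerHemi(parc)
  cnt <- vapply(maps, function(m) {
    countPositiveElements(m, parc, thresholdBasis)[seq_len(2L * p)]
  }, integer(2L * p))
  subjectIds <- vapply(maps, subjectId, character(1))
  contrasts <- vapply(maps, contrastName, character(1))
  key <- paste(subjectIds, contrasts, sep = ".")
  if (anyDuplicated(key))
    stop("duplicate subject x contrast map: ", key[anyDuplicated(key)])
  colnames(cnt) <- key
  cd <- DataFrame(subject_id = subjectIds, contrast = contrasts,
                  row.names = key)
  if (!is.null(subjects)) {
    i <- match(subjectIds, subjects$subject_id)
    if (anyNA(i)) stop("map subject missing from 'subjects': ",
                       subjectIds[which(is.na(i))[1]])
    cd$handedness <- subjects$handedness[i]
    cd$ehi <- subjects$ehi[i]
  }
  parsed <- parseRegionLabel(parcelLabels(parc))
  rd <- DataFrame(label = parcelLabels(parc), side = parsed$side,
                  area = parsed$area, row.names = parcelLabels(parc))
  se <- SummarizedExperiment(assays = list(counts = cnt), rowData = rd,
                             colData = cd,
                             metadata = list(threshold_basis = thresholdBasis))
  new("PECountTable", se)
}

#' Hemisphere and whole-surface PE totals
#'
#' Totals are always re-derived from the per-parcel counts, so
#' `total_surface == total_left + total_right` holds by construction.
#'
#' @param x a [PECountTable-class].
#' @return A data.frame (one row per sample) with `subject_id`, `contrast`,
#'   `total_left`, `total_right`, `total_surface`.
#' @export
peTotals <- function(x) {
  stopifnot(is(x, "PECountTable"))
  cnt <- assay(x, "counts")
  left <- rowData(x)$side == "left"
  tl <- colSums(cnt[left, , drop = FALSE])
  tr <- colSums(cnt[!left, , drop = FALSE])
  data.frame(subject_id = colData(x)$subject_id,
             contrast = colData(x)$contrast,
             total_left = as.integer(tl), total_right = as.integer(tr),
             total_surface = as.integer(tl + tr),
             row.names = colnames(x))
}

setMethod("show", "PECountTable", function(object) {
  cat("PECountTable:", nrow(object), "sided parcels x", ncol(object),
      "subject-contrast samples\n")
  tot <- peTotals(object)
  cat("  surface totals: median", median(tot$total_surface),
      "PEs (range", min(tot$total_surface), "-",
      max(tot$total_surface), ")\n")
  cat("  threshold basis:",
      metadata(object)$threshold_basis %||% "full_map", "\n")
})

#' Read / write a PE count table TSV
#'
#' One row per subject x contrast; columns `subject_id`, `contrast`, one
#' integer count per sided parcel label, then `total_left`, `total_right`,
#' `total_surface`. On reading, the stored totals are checked against the
#' re-summed parcel counts.
#'
#' @param x a [PECountTable-class].
#' @param path file path.
#' @return `readPECountTable()` returns a [PECountTable-class].
#' @export
writePECountTable <- function(x, path) {
  stopifnot(is(x, "PECountTable"))
  cnt <- t(assay(x, "counts"))
  tot <- peTotals(x)
  df <- cbind(data.frame(subject_id = colData(x)$subject_id,
                         contrast = colData(x)$contrast),
              as.data.frame(cnt),
              tot[, c("total_left", "total_right", "total_surface")])
  writeTsv(df, path)
}

#' @rdname writePECountTable
#' @param subjects optional subject metadata to re-attach.
#' @export
readPECountTable <- function(path, subjects = NULL) {
  df <- readTsv(path)
  fixed <- c("subject_id", "contrast", "total_left", "total_right",
             "total_surface")
  if (!all(fixed %in% colnames(df)))
    stop("PE count file '", path, "' must have columns ",
         paste(fixed, collapse = ", "))
  labCols <- setdiff(colnames(df), fixed)
  parsed <- parseRegionLabel(labCols)
  if (any(parsed$side == "unsided"))
    stop("PE count columns must use sided labels")
  cnt <- t(as.matrix(df[, labCols, drop = FALSE]))
  storage.mode(cnt) <- "integer"
  left <- parsed$side == "left"
  if (!all(colSums(cnt[left, , drop = FALSE]) == df$total_left) ||
      !all(colSums(cnt[!left, , drop = FALSE]) == df$total_right) ||
      !all(df$total_left + df$total_right == df$total_surface))
    stop("stored totals inconsistent with parcel counts in '", path, "'")
  key <- paste(df$subject_id, df$contrast, sep = ".")
  colnames(cnt) <- key
  cd <- DataFrame(subject_id = df$subject_id, contrast = df$contrast,
                  row.names = key)
  if (!is.null(subjects)) {
    i <- match(df$subject_id, subjects$subject_id)
    cd$handedness <- subjects$handedness[i]
    cd$ehi <- subjects$ehi[i]
  }
  rd <- DataFrame(label = labCols, side = parsed$side, area = parsed$area,
                  row.names = labCols)
  se <- SummarizedExperiment(assays = list(counts = cnt), rowData = rd,
                             colData = cd)
  new("PECountTable", se)
}
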