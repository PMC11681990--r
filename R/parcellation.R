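#' Parse a sided cortical-area label
#'
#' Region labels come in two dialects: sided (`L_A5_ROI`, `R_PGi_ROI`) and
#' unsided (`A5_ROI`), the latter used when paired hemispheric tests collapse
#' the two sides of one area. Only the leading `L_`/`R_` and the trailing
#' `_ROI` are structural; area names may contain internal underscores or
#' hyphens (`9_46d`, `a9-46v`).
#'
#' @param label character vector of labels.
#' @return A data.frame with columns `side` (`"left"`, `"right"` or
#'   `"unsided"`) and `area`.
#' @examples
#' parseRegionLabel(c("R_A5_ROI", "L_PGi_ROI", "A5_ROI"))
#' @export
parseRegionLabel <- function(label) {
  label <- as.character(label)
  ok <- grepl("^(.+)_ROI$", label)
  if (any(!ok))
    stop("malformed region label: '", label[which(!ok)[1]], "'")
  core <- sub("_ROI$", "", label)
  side <- rep("unsided", length(label))
  side[startsWith(core, "L_")] <- "left"
  side[startsWith(core, "R_")] <- "right"
  area <- ifelse(side == "unsided", core, substring(core, 3L))
  if (any(!nzchar(area)))
    stop("malformed region label: '", label[which(!nzchar(area))[1]], "'")
  data.frame(side = side, area = area)
}

#' Construct a mirrored parcellation
#'
#' @param areaNames character vector of per-hemisphere area names (without
#'   side prefix or `_ROI` suffix).
#' @param assignmentLeft,assignmentRight integer vectors mapping each vertex
#'   (1-based, in mesh order) to an index of `areaNames`.
#' @return A [Parcellation-class] object.
#' @export
parcellation <- function(areaNames, assignmentLeft, assignmentRight) {
  new("Parcellation", areaNames = as.character(areaNames),
      assignmentLeft = as.integer(assignmentLeft),
      assignmentRight = as.integer(assignmentRight))
}

#' Parcellation accessors
#'
#' @param x a [Parcellation-class].
#' @return `nParcelsPerHemi()`: number of areas per hemisphere;
#'   `areaNames()`: the area names; `parcelLabels()`: the `2 * P` sided
#'   labels (left block then right block); `parcelAssignment()`: the
#'   per-vertex area index of one hemisphere; `parcelSizes()`: vertex count
#'   per sided parcel.
#' @export
nParcelsPerHemi <- function(x) length(x@areaNames)

#' @rdname nParcelsPerHemi
#' @export
areaNames <- function(x) x@areaNames

#' @rdname nParcelsPerHemi
#' @export
parcelLabels <- function(x) {
  c(sidedLabel(rep("left", nParcelsPerHemi(x)), x@areaNames),
    sidedLabel(rep("right", nParcelsPerHemi(x)), x@areaNames))
}

#' @rdname nParcelsPerHemi
#' @param hemisphere `"left"` or `"right"`.
#' @export
parcelAssignment <- function(x, hemisphere = c("left", "right")) {
  switch(match.arg(hemisphere),
         left = x@assignmentLeft, right = x@assignmentRight)
}

#' @rdname nParcelsPerHemi
#' @export
parcelSizes <- function(x) {
  p <- nParcelsPerHemi(x)
  setNames(c(tabulate(x@assignmentLeft, nbins = p),
             tabulate(x@assignmentRight, nbins = p)),
           parcelLabels(x))
}

setMethod("show", "Parcellation", function(object) {
  cat("Parcellation:", nParcelsPerHemi(object), "areas per hemisphere,",
      length(object@assignmentLeft), "vertices per hemisphere\n")
  lab <- head(areaNames(object), 4L)
  cat("  areas:", paste(lab, collapse = ", "),
      if (nParcelsPerHemi(object) > 4L) "..." else "", "\n")
})

#' Read / write a parcellation TSV
#'
#' The parcellation TSV has columns `hemisphere` (`L`/`R`), `vertex`
#' (0-based within hemisphere) and `label` (sided, `L_<area>_ROI` /
#' `R_<area>_ROI`). Every vertex must appear exactly once per hemisphere
#' (full partition) and every area must be present on both hemispheres
#' (mirror invariant).
#'
#' @param path file path.
#' @return `readParcellation()` returns a [Parcellation-class];
#'   `writeParcellation()` invisibly returns `path`.
#' @export
readParcellation <- function(path) {
  df <- readTsv(path)
  need <- c("hemisphere", "vertex", "label")
  if (!all(need %in% colnames(df)))
    stop("parcellation file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  if (any(!df$hemisphere %in% c("L", "R")))
    stop("unknown hemisphere tag in '", path, "'")
  parsed <- parseRegionLabel(df$label)
  expectSide <- ifelse(df$hemisphere == "L", "left", "right")
  if (any(parsed$side != expectSide))
    stop("label '", df$label[which(parsed$side != expectSide)[1]],
         "' does not match its hemisphere column in '", path, "'")
  areasL <- sort(unique(parsed$area[parsed$side == "left"]))
  areasR <- sort(unique(parsed$area[parsed$side == "right"]))
  if (!identical(areasL, areasR)) {
    orphan <- c(setdiff(areasL, areasR), setdiff(areasR, areasL))
    stop("unmirrored parcel label(s): ",
         paste(orphan, collapse = ", "), " in '", path, "'")
  }
  sideAssign <- function(tag) {
    sub <- which(df$hemisphere == tag)
    v <- as.integer(df$vertex[sub])
    if (anyDuplicated(v))
      stop("vertex ", v[anyDuplicated(v)], " assigned twice on hemisphere ",
           tag, " in '", path, "'")
    if (!setequal(v, seq_along(sub) - 1L))
      stop("hemisphere ", tag, " of '", path,
           "' is not a full 0..n-1 vertex partition")
    match(parsed$area[sub], areasL)[order(v)]
  }
  parcellation(areasL, sideAssign("L"), sideAssign("R"))
}

#' @rdname readParcellation
#' @param x a [Parcellation-class] to serialize.
#' @export
writeParcellation <- function(x, path) {
  stopifnot(is(x, "Parcellation"))
  n <- length(x@assignmentLeft)
  df <- data.frame(
    hemisphere = rep(c("L", "R"), each = n),
    vertex = rep(seq_len(n) - 1L, 2L),
    label = c(sidedLabel(rep("left", n), x@areaNames[x@assignmentLeft]),
              sidedLabel(rep("right", n), x@areaNames[x@assignmentRight]))
  )
  writeTsv(df, path)
}
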