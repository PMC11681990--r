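#' Construct a vertex-level statistical map
#'
#' @param subjectId single string identifying the subject.
#' @param contrast one of [peContrasts()].
#' @param valuesLeft,valuesRight numeric vectors of per-vertex statistic
#'   values (z scale), one per hemisphere, equal lengths.
#'
#' @return A [VertexScalarMap-class] object.
#' @examples
#' m <- vertexScalarMap("S01", "STORY", c(-1, 0.6), c(0.5, 2))
#' nVerticesPerHemi(m)
#' @export
vertexScalarMap <- function(subjectId, contrast, valuesLeft, valuesRight) {
  new("VertexScalarMap", subjectId = as.character(subjectId),
      contrast = as.character(contrast),
      valuesLeft = as.numeric(valuesLeft),
      valuesRight = as.numeric(valuesRight))
}

#' @describeIn vertexScalarMap number of vertices per hemisphere.
#' @param x a `VertexScalarMap`.
#' @export
nVerticesPerHemi <- function(x) {
  stopifnot(is(x, "VertexScalarMap"))
  length(x@valuesLeft)
}

#' Accessors for VertexScalarMap
#'
#' @param x a [VertexScalarMap-class].
#' @return `mapValues()` returns the per-vertex values of one hemisphere (or
#'   both pooled, left then right); `subjectId()` and `contrastName()` the
#'   identifying fields.
#' @export
mapValues <- function(x, hemisphere = c("both", "left", "right")) {
  stopifnot(is(x, "VertexScalarMap"))
  switch(match.arg(hemisphere),
         left = x@valuesLeft,
         right = x@valuesRight,
         both = c(x@valuesLeft, x@valuesRight))
}

#' @rdname mapValues
#' @param hemisphere which hemisphere to return.
#' @export
subjectId <- function(x) x@subjectId

#' @rdname mapValues
#' @export
contrastName <- function(x) x@contrast

setMethod("show", "VertexScalarMap", function(object) {
  cat("VertexScalarMap:", object@subjectId, "/", object@contrast, "\n")
  cat(" ", length(object@valuesLeft), "vertices per hemisphere\n")
  cat("  value range [",
      formatReal(min(mapValues(object))), ", ",
      formatReal(max(mapValues(object))), "]\n", sep = "")
})

#' Read / write a dense vertex map in the package's TSV dialect
#'
#' The dense-map TSV has columns `hemisphere` (`L`/`R`), `vertex` (0-based
#' index within the hemisphere) and `value`; one file per subject x contrast.
#'
#' @param path file path.
#' @param expectedVertices required number of vertices per hemisphere.
#' @param subjectId,contrast identity of the map (not stored in the file).
#' @return `readVertexMap()` returns a [VertexScalarMap-class];
#'   `writeVertexMap()` invisibly returns `path`.
#' @export
readVertexMap <- function(path, expectedVertices, subjectId, contrast) {
  df <- readTsv(path)
  need <- c("hemisphere", "vertex", "value")
  if (!all(need %in% colnames(df)))
    stop("dense-map file '", path, "' must have columns ",
         paste(need, collapse = ", "))
  bad <- which(!df$hemisphere %in% c("L", "R"))
  if (length(bad))
    stop("unknown hemisphere tag '", df$hemisphere[bad[1]],
         "' at line ", bad[1] + 1L, " of '", path, "'")
  vals <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(vals))
  if (length(bad))
    stop("non-numeric value '", df$value[bad[1]], "' at line ",
         bad[1] + 1L, " of '", path, "'")
  sideVals <- function(tag) {
    sub <- df[df$hemisphere == tag, , drop = FALSE]
    v <- suppressWarnings(as.integer(sub$vertex))
    if (anyNA(v) || anyDuplicated(v) ||
        !setequal(v, seq_len(nrow(sub)) - 1L))
      stop("hemisphere ", tag, " of '", path,
           "' must index vertices 0..n-1 exactly once")
    as.numeric(sub$value)[order(v)]
  }
  vl <- sideVals("L"); vr <- sideVals("R")
  if (length(vl) != expectedVertices || length(vr) != expectedVertices)
    stop("'", path, "': expected ", expectedVertices,
         " vertices per hemisphere, found ", length(vl), " (L) / ",
         length(vr), " (R)")
  vertexScalarMap(subjectId, contrast, vl, vr)
}

#' @rdname readVertexMap
#' @param map a [VertexScalarMap-class] to serialize.
#' @export
writeVertexMap <- function(map, path) {
  stopifnot(is(map, "VertexScalarMap"))
  n <- nVerticesPerHemi(map)
  df <- data.frame(
    hemisphere = rep(c("L", "R"), each = n),
    vertex = rep(seq_len(n) - 1L, 2L),
    value = c(map@valuesLeft, map@valuesRight)
  )
  writeTsv(df, path, realCols = "value")
}
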