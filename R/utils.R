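## Shared internal helpers: label construction, serialization, seed streams.

# Sided label construction; inverse of parseRegionLabel for clean area names.
sidedLabel <- function(side, area) {
  if (!length(side)) return(character(0))
  prefix <- c(left = "L_", right = "R_", unsided = "")[side]
  paste0(prefix, area, "_ROI")
}

# Decimal formatting with enough significant digits for reproducible
# round-trips of doubles through text tables.
formatReal <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- "NA"
  out
}

writeTsv <- function(df, path, realCols = NULL) {
  for (cl in intersect(realCols, colnames(df))) df[[cl]] <- formatReal(df[[cl]])
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

# Counter-based per-subject seed derivation: subject i's seed depends only on
# the master seed and i, so growing a cohort never reshuffles earlier
# subjects. Two LCG mixing rounds; all intermediates stay below 2^53 and the
# result below 2^31.
deriveSeed <- function(masterSeed, counter) {
  m <- 2147483647
  s <- as.numeric(masterSeed) %% m
  s <- (s * 48271 + as.numeric(counter) * 16807 + 12345) %% m
  s <- (s * 69621 + 1013904223 %% m) %% m
  as.integer(s)
}

# Canonical JSON (recursively key-sorted, NULLs dropped) -> md5, for the
# run manifest's config hash.
canonicalConfigJson <- function(x) {
  canon <- function(v) {
    if (is.list(v)) {
      v <- v[!vapply(v, is.null, logical(1))]
      nm <- names(v)
      if (!is.null(nm) && any(nzchar(nm))) v <- v[order(nm)]
      lapply(v, canon)
    } else v
  }
  jsonlite::toJSON(canon(x), auto_unbox = TRUE, digits = NA)
}

configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(canonicalConfigJson(x)), tmp)
  unname(tools::md5sum(tmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
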