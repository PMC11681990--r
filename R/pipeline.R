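## The three comparison designs over a PE count table: whole-hemisphere
## paired totals, per-area paired hemispheric tests within a group, and
## per-sided-parcel independent tests between handedness groups.

selectSamples <- function(pe, contrast, groupFilter = "all") {
  cd <- colData(pe)
  keep <- cd$contrast == contrast
  if (groupFilter != "all") {
    if (is.null(cd$handedness))
      stop("group filtering requires subject handedness in colData")
    keep <- keep & cd$handedness == groupFilter
  }
  if (!any(keep)) stop("no samples selected for contrast '", contrast,
                       "', group '", groupFilter, "'")
  which(keep)
}

#' Whole-hemisphere paired comparison of PE totals
#'
#' Yuen's paired trimmed-mean test on the per-subject
#' (`total_left`, `total_right`) pairs. The mean difference is oriented
#' left - right: positive values indicate left-hemisphere dominance.
#'
#' @param pe a [PECountTable-class].
#' @param contrast which contrast's samples to use.
#' @param groupFilter `"all"`, `"LH"` or `"RH"`.
#' @param trim trimming proportion.
#' @return A [RobustTestResult-class] with `direction = "left_minus_right"`.
#' @export
hemisphericComparison <- function(pe, contrast = "STORY",
                                  groupFilter = c("all", "LH", "RH"),
                                  trim = 0.2) {
  groupFilter <- match.arg(groupFilter)
  idx <- selectSamples(pe, contrast, groupFilter)
  if (length(idx) < 5L)
    stop("need at least 5 subjects after filtering, have ", length(idx))
  tot <- peTotals(pe)[idx, ]
  r <- .yuenPairedCore(tot$total_left, tot$total_right, trim)
  newRobustResult("", r$statistic, r$df, r$diff, r$ciLow, r$ciHigh, r$p,
                  r$xi, "left_minus_right", r$n)
}

#' Per-area paired hemispheric tests within a group
#'
#' One Yuen paired test per cortical area on the (right-parcel count,
#' left-parcel count) pairs across subjects. The mean difference is
#' oriented right - left: positive values (and positive xi) indicate more
#' PEs in the right hemisphere, matching the published tables' convention.
#' BH correction is applied across the `nParcelsPerHemi` tests of this
#' family only.
#'
#' @inheritParams hemisphericComparison
#' @param alphaFamily ignored by the tests themselves; filtering happens in
#'   [summarizeSignificant()].
#' @return A data.frame (one row per area, unsided `region` labels) with
#'   columns `region`, `statistic`, `df`, `mean_difference`, `ci_low`,
#'   `ci_high`, `p`, `p_corrected`, `xi`; attribute `direction` is
#'   `"right_minus_left"`.
#' @export
withinGroupParcelTests <- function(pe, contrast = "STORY",
                                   groupFilter = c("all", "LH", "RH"),
                                   trim = 0.2) {
  groupFilter <- match.arg(groupFilter)
  idx <- selectSamples(pe, contrast, groupFilter)
  cnt <- assay(pe, "counts")[, idx, drop = FALSE]
  rd <- rowData(pe)
  areas <- unique(rd$area)
  rowsL <- match(paste0("L_", areas, "_ROI"), rd$label)
  rowsR <- match(paste0("R_", areas, "_ROI"), rd$label)
  if (anyNA(rowsL) || anyNA(rowsR))
    stop("unmirrored parcel label in PE table")
  res <- lapply(seq_along(areas), function(i) {
    .yuenPairedCore(cnt[rowsR[i], ], cnt[rowsL[i], ], trim)
  })
  out <- data.frame(
    region = paste0(areas, "_ROI"),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    mean_difference = vapply(res, `[[`, numeric(1), "diff"),
    ci_low = vapply(res, `[[`, numeric(1), "ciLow"),
    ci_high = vapply(res, `[[`, numeric(1), "ciHigh"),
    p = vapply(res, `[[`, numeric(1), "p"),
    xi = vapply(res, `[[`, numeric(1), "xi")
  )
  out$p_corrected <- bhAdjust(out$p)
  out <- out[, c("region", "statistic", "df", "mean_difference", "ci_low",
                 "ci_high", "p", "p_corrected", "xi")]
  attr(out, "direction") <- "right_minus_left"
  attr(out, "design") <- "within_group_parcels"
  attr(out, "n_tests") <- length(areas)
  out
}

#' Per-sided-parcel independent tests between handedness groups
#'
#' One Yuen independent-samples test per sided parcel comparing left-handed
#' against right-handed subjects' PE counts. The mean difference is
#' oriented LH - RH: positive values (and positive xi) are in the direction
#' of left-handedness. BH correction runs across all
#' `2 * nParcelsPerHemi` tests of the family.
#'
#' @inheritParams hemisphericComparison
#' @return A data.frame as in [withinGroupParcelTests()] but with sided
#'   `region` labels and attribute `direction = "LH_minus_RH"`.
#' @export
betweenGroupParcelTests <- function(pe, contrast = "STORY", trim = 0.2) {
  cd <- colData(pe)
  if (is.null(cd$handedness))
    stop("between-group tests require subject handedness in colData")
  idxLH <- selectSamples(pe, contrast, "LH")
  idxRH <- selectSamples(pe, contrast, "RH")
  cnt <- assay(pe, "counts")
  labels <- rowData(pe)$label
  res <- lapply(seq_along(labels), function(i) {
    .yuenIndependentCore(cnt[i, idxLH], cnt[i, idxRH], trim)
  })
  out <- data.frame(
    region = labels,
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    df = vapply(res, `[[`, numeric(1), "df"),
    mean_difference = vapply(res, `[[`, numeric(1), "diff"),
    ci_low = vapply(res, `[[`, numeric(1), "ciLow"),
    ci_high = vapply(res, `[[`, numeric(1), "ciHigh"),
    p = vapply(res, `[[`, numeric(1), "p"),
    xi = vapply(res, `[[`, numeric(1), "xi")
  )
  out$p_corrected <- bhAdjust(out$p)
  out <- out[, c("region", "statistic", "df", "mean_difference", "ci_low",
                 "ci_high", "p", "p_corrected", "xi")]
  attr(out, "direction") <- "LH_minus_RH"
  attr(out, "design") <- "between_group_parcels"
  attr(out, "n_tests") <- length(labels)
  out
}

#' Filter and order a results table the way the published tables are shown
#'
#' Keeps rows with `p_corrected <= alpha` (boundary inclusive) and orders
#' them by descending signed xi: the positive block first in decreasing
#' order, then the negative block in decreasing order.
#'
#' @param results data.frame from one comparison design.
#' @param alpha FDR level (default 0.05).
#' @return The filtered, reordered data.frame (attributes preserved).
#' @export
summarizeSignificant <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("p_corrected", "xi") %in% colnames(results)))
  keep <- results[results$p_corrected <= alpha, , drop = FALSE]
  keep <- keep[order(keep$xi, decreasing = TRUE), , drop = FALSE]
  rownames(keep) <- NULL
  for (a in c("direction", "design"))
    attr(keep, a) <- attr(results, a)
  attr(keep, "alpha") <- alpha
  keep
}

#' Mann-Whitney comparisons of subject covariates between two groups
#'
#' Runs [mannWhitney()] for each covariate between the two levels of a
#' grouping column (first level minus second level, by sorted level order
#' unless `levels` is given) and BH-adjusts the p-values across the listed
#' covariates.
#'
#' @param subjects data.frame of per-subject metadata.
#' @param covariates character vector of numeric column names to compare.
#' @param group name of the two-level grouping column (default
#'   `"handedness"`).
#' @param levels optional length-2 character vector fixing the orientation
#'   (shift = first minus second).
#' @return A data.frame with columns `covariate`, `statistic`, `p`,
#'   `p_corrected`, `shift`, `ci_low`, `ci_high`.
#' @export
compareMetadata <- function(subjects, covariates, group = "handedness",
                            levels = NULL) {
  stopifnot(is.data.frame(subjects), group %in% colnames(subjects))
  g <- as.character(subjects[[group]])
  if (is.null(levels)) levels <- sort(unique(g))
  if (length(levels) != 2L)
    stop("grouping column must have exactly two levels")
  missing <- setdiff(covariates, colnames(subjects))
  if (length(missing))
    stop("unknown covariate(s): ", paste(missing, collapse = ", "))
  rows <- lapply(covariates, function(cv) {
    x <- subjects[[cv]][g == levels[1]]
    y <- subjects[[cv]][g == levels[2]]
    r <- mannWhitney(x, y)
    data.frame(covariate = cv, statistic = r@statistic, p = r@pValue,
               shift = r@hlShift, ci_low = r@ciLow, ci_high = r@ciHigh)
  })
  out <- do.call(rbind, rows)
  out$p_corrected <- bhAdjust(out$p)
  out[, c("covariate", "statistic", "p", "p_corrected", "shift",
          "ci_low", "ci_high")]
}

#' Write / read a results table TSV
#'
#' Serializes the column set of the published tables (`region`,
#' `statistic`, `mean_difference`, `ci_low`, `ci_high`, `p`, `p_corrected`,
#' `xi`) with full double precision. With `ordering = "by_xi"` rows are
#' written in descending signed-xi order; `"as_is"` preserves input order.
#'
#' @param results data.frame of test results.
#' @param path file path.
#' @param ordering `"by_xi"` or `"as_is"`.
#' @return `readResultsTable()` returns the data.frame.
#' @export
writeResultsTable <- function(results, path, ordering = c("by_xi", "as_is")) {
  ordering <- match.arg(ordering)
  cols <- c("region", "statistic", "mean_difference", "ci_low", "ci_high",
            "p", "p_corrected", "xi")
  stopifnot(is.data.frame(results))
  if (nrow(results) && !all(cols %in% colnames(results)))
    stop("results must have columns ", paste(cols, collapse = ", "))
  if (!nrow(results)) {
    results <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)),
                                      cols))
    results$region <- character(0)
  }
  df <- results[, cols, drop = FALSE]
  if (ordering == "by_xi" && nrow(df))
    df <- df[order(df$xi, decreasing = TRUE), , drop = FALSE]
  writeTsv(df, path, realCols = setdiff(cols, "region"))
}

#' @rdname writeResultsTable
#' @export
readResultsTable <- function(path) {
  df <- readTsv(path)
  cols <- c("region", "statistic", "mean_difference", "ci_low", "ci_high",
            "p", "p_corrected", "xi")
  if (!all(cols %in% colnames(df)))
    stop("results file '", path, "' must have columns ",
         paste(cols, collapse = ", "))
  for (cl in setdiff(cols, "region")) df[[cl]] <- as.numeric(df[[cl]])
  df
}
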