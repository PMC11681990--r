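## S4 class definitions for the surface model, synthetic cohorts and results.

#' Contrast names understood by the package
#'
#' Task contrasts of the language paradigm: `"STORY"` (story listening vs
#' baseline) and `"STORY_MATH"` (story vs arithmetic control).
#'
#' @export
peContrasts <- function() c("STORY", "STORY_MATH")

#' VertexScalarMap: one subject x contrast vertex-level statistical map
#'
#' Per-vertex statistic values (z scale, unthresholded, negatives permitted)
#' on two mirrored hemispheric surface meshes. Hemispheres are stored
#' separately; vertex order is the mesh order, 0-based in files and 1-based
#' in R.
#'
#' @slot subjectId character(1) opaque subject identifier.
#' @slot contrast character(1), one of [peContrasts()].
#' @slot valuesLeft,valuesRight numeric vectors of equal length, finite.
#'
#' @seealso [vertexScalarMap()], [readVertexMap()], [writeVertexMap()]
#' @export
setClass("VertexScalarMap",
  representation(
    subjectId = "character",
    contrast = "character",
    valuesLeft = "numeric",
    valuesRight = "numeric"
  )
)

setValidity("VertexScalarMap", function(object) {
  msg <- character(0)
  if (length(object@subjectId) != 1L || is.na(object@subjectId) ||
      !nzchar(object@subjectId))
    msg <- c(msg, "'subjectId' must be a single non-empty string")
  if (length(object@contrast) != 1L || !object@contrast %in% peContrasts())
    msg <- c(msg, sprintf("'contrast' must be one of %s",
                          paste(peContrasts(), collapse = ", ")))
  if (length(object@valuesLeft) != length(object@valuesRight))
    msg <- c(msg, "hemispheres must have equal vertex counts (mirrored meshes)")
  if (length(object@valuesLeft) < 1L)
    msg <- c(msg, "map must contain at least one vertex per hemisphere")
  if (!all(is.finite(object@valuesLeft)) || !all(is.finite(object@valuesRight)))
    msg <- c(msg, "vertex values must be finite")
  if (length(msg)) msg else TRUE
})

#' Parcellation: mirrored vertex-to-parcel assignment
#'
#' Assigns every vertex of each hemisphere to exactly one of
#' `nParcelsPerHemi` cortical areas. Area names are shared between
#' hemispheres; sided labels are `L_<area>_ROI` / `R_<area>_ROI`.
#'
#' @slot areaNames character vector of unique per-hemisphere area names
#'   (no `L_`/`R_` prefix, no `_ROI` suffix).
#' @slot assignmentLeft,assignmentRight integer vectors (one element per
#'   vertex) of indices into `areaNames`; a full partition, no unassigned
#'   vertices.
#'
#' @seealso [makeParcellation()], [readParcellation()], [parcelLabels()]
#' @export
setClass("Parcellation",
  representation(
    areaNames = "character",
    assignmentLeft = "integer",
    assignmentRight = "integer"
  )
)

setValidity("Parcellation", function(object) {
  msg <- character(0)
  p <- length(object@areaNames)
  if (p < 1L) msg <- c(msg, "at least one parcel per hemisphere required")
  if (anyDuplicated(object@areaNames))
    msg <- c(msg, "area names must be unique")
  if (any(!nzchar(object@areaNames)) || anyNA(object@areaNames))
    msg <- c(msg, "area names must be non-empty strings")
  for (side in c("assignmentLeft", "assignmentRight")) {
    a <- slot(object, side)
    if (length(a) < 1L || anyNA(a) || any(a < 1L) || any(a > p))
      msg <- c(msg, sprintf("'%s' must assign every vertex to a parcel index in 1..%d",
                            side, p))
  }
  if (length(object@assignmentLeft) != length(object@assignmentRight))
    msg <- c(msg, "hemispheres must have equal vertex counts")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortSpec: parameters of the synthetic cohort generator
#'
#' Defines a cohort of `2 * nPerGroup` subjects (left- and right-handed
#' groups) whose vertex maps are generated as
#' `baselineMu + a_p + s * delta_p / 2 + 1[LH] * g_(sided parcel) + u_subject
#' + eps_vertex`, with `s = +1` on the left hemisphere and `-1` on the right,
#' `u ~ N(0, subjectSd^2)` once per subject and `eps ~ N(0, vertexSd^2)`
#' i.i.d. per vertex (optionally contaminated by an inflated-sd Gaussian
#' component).
#'
#' @slot nPerGroup integer, subjects per handedness group.
#' @slot nParcelsPerHemi integer, areas per hemisphere.
#' @slot verticesPerParcel integer, vertices in each parcel.
#' @slot baselineMu numeric(1) baseline map value.
#' @slot parcelActivation numeric, per-area activation `a_p`
#'   (length `nParcelsPerHemi`).
#' @slot lateralityDelta numeric, per-area left-minus-right asymmetry
#'   `delta_p` (positive = left-dominant; length `nParcelsPerHemi`).
#' @slot groupEffect numeric, per *sided* parcel additive effect applied to
#'   left-handed subjects only (length `2 * nParcelsPerHemi`, left block then
#'   right block).
#' @slot subjectSd,vertexSd numeric standard deviations (subject random
#'   effect; vertex noise).
#' @slot contaminationProb,contaminationScale numeric: with probability
#'   `contaminationProb` a vertex draws its noise from
#'   `N(0, (contaminationScale * vertexSd)^2)` (heavy-tailed option).
#' @slot contrast character(1), one of [peContrasts()].
#' @slot seed integer master seed.
#'
#' @seealso [syntheticCohortSpec()], [simulateCohort()]
#' @export
setClass("SyntheticCohortSpec",
  representation(
    nPerGroup = "integer",
    nParcelsPerHemi = "integer",
    verticesPerParcel = "integer",
    baselineMu = "numeric",
    parcelActivation = "numeric",
    lateralityDelta = "numeric",
    groupEffect = "numeric",
    subjectSd = "numeric",
    vertexSd = "numeric",
    contaminationProb = "numeric",
    contaminationScale = "numeric",
    contrast = "character",
    seed = "integer"
  )
)

setValidity("SyntheticCohortSpec", function(object) {
  msg <- character(0)
  p <- object@nParcelsPerHemi
  if (length(object@nPerGroup) != 1L || object@nPerGroup < 1L)
    msg <- c(msg, "'nPerGroup' must be a positive integer")
  if (length(p) != 1L || p < 1L)
    msg <- c(msg, "'nParcelsPerHemi' must be a positive integer")
  if (length(object@verticesPerParcel) != 1L || object@verticesPerParcel < 1L)
    msg <- c(msg, "'verticesPerParcel' must be a positive integer")
  if (length(object@parcelActivation) != p)
    msg <- c(msg, "'parcelActivation' must have length nParcelsPerHemi")
  if (length(object@lateralityDelta) != p)
    msg <- c(msg, "'lateralityDelta' must have length nParcelsPerHemi")
  if (length(object@groupEffect) != 2L * p)
    msg <- c(msg, "'groupEffect' must have length 2 * nParcelsPerHemi (left block, right block)")
  if (object@subjectSd < 0) msg <- c(msg, "'subjectSd' must be >= 0")
  if (object@vertexSd <= 0) msg <- c(msg, "'vertexSd' must be > 0")
  if (object@contaminationProb < 0 || object@contaminationProb > 1)
    msg <- c(msg, "'contaminationProb' must be in [0, 1]")
  if (object@contaminationScale < 1)
    msg <- c(msg, "'contaminationScale' must be >= 1")
  if (!object@contrast %in% peContrasts())
    msg <- c(msg, "unknown contrast")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' PECountTable: positive-element counts as a SummarizedExperiment
#'
#' Rows are sided parcels (left-hemisphere block then right-hemisphere
#' block; `rowData` columns `label`, `side`, `area`), columns are
#' subject x contrast samples (`colData` columns `subject_id`, `contrast`,
#' and, when available, `handedness` and `ehi`). The single assay `counts`
#' holds nonnegative integer PE counts. Hemisphere and whole-surface totals
#' are always derived from the counts via [peTotals()], so the totals
#' invariants hold by construction.
#'
#' @seealso [peCountTable()], [peTotals()], [writePECountTable()]
#' @export
setClass("PECountTable", contains = "SummarizedExperiment")

setValidity("PECountTable", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(cnt < 0) || any(cnt != round(cnt)))
      msg <- c(msg, "PE counts must be nonnegative integers")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("label", "side", "area") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'label', 'side', 'area'")
  else if (!all(rd$side %in% c("left", "right")))
    msg <- c(msg, "rowData$side must be 'left' or 'right'")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("subject_id", "contrast") %in% colnames(cd)))
    msg <- c(msg, "colData must contain 'subject_id' and 'contrast'")
  if (length(msg)) msg else TRUE
})

#' TrimmedSummary: trimmed mean with standard error and confidence interval
#'
#' @slot trimmedMean numeric(1) the gamma-trimmed mean.
#' @slot se numeric(1) standard error `s_w / ((1 - 2*gamma) * sqrt(n))`, with
#'   `s_w` the winsorized SD (divisor `n - 1`).
#' @slot ciLow,ciHigh numeric(1) symmetric t interval with `h - 1` df.
#' @slot n,h integer: sample size and effective size `n - 2 * floor(gamma*n)`.
#' @slot trim,conf numeric: trimming proportion and confidence level.
#'
#' @seealso [trimmedMeanSummary()]
#' @export
setClass("TrimmedSummary",
  representation(
    trimmedMean = "numeric", se = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    n = "integer", h = "integer", trim = "numeric", conf = "numeric"
  )
)

setValidity("TrimmedSummary", function(object) {
  msg <- character(0)
  if (object@se < 0) msg <- c(msg, "'se' must be >= 0")
  if (object@trim < 0 || object@trim >= 0.5)
    msg <- c(msg, "'trim' must be in [0, 0.5)")
  if (!(object@ciLow <= object@trimmedMean &&
        object@trimmedMean <= object@ciHigh))
    msg <- c(msg, "interval must bracket the trimmed mean")
  if (length(msg)) msg else TRUE
})

#' RobustTestResult: outcome of a robust trimmed-mean comparison
#'
#' @slot parcelLabel character(1) region label ("" for whole-hemisphere
#'   comparisons).
#' @slot statistic numeric(1) Yuen t statistic.
#' @slot df numeric(1) degrees of freedom (`h - 1` paired;
#'   Welch-Satterthwaite analog independent).
#' @slot meanDifference numeric(1) trimmed-mean difference in the design's
#'   orientation (see `direction`).
#' @slot ciLow,ciHigh numeric(1) 95% confidence bounds for the difference.
#' @slot pRaw,pCorrected numeric(1): two-sided p and its BH-adjusted value
#'   (`NA` until a multiple-testing family is formed).
#' @slot xi numeric(1) signed explanatory effect size, in `[-1, 1]`, sign
#'   matching `meanDifference`.
#' @slot direction character(1) sign convention, e.g. `"right_minus_left"`.
#' @slot n integer vector of sample sizes (1 value paired, 2 independent).
#'
#' @seealso [yuenPaired()], [yuenIndependent()]
#' @export
setClass("RobustTestResult",
  representation(
    parcelLabel = "character",
    statistic = "numeric", df = "numeric",
    meanDifference = "numeric",
    ciLow = "numeric", ciHigh = "numeric",
    pRaw = "numeric", pCorrected = "numeric",
    xi = "numeric", direction = "character", n = "integer"
  ),
  prototype(parcelLabel = "", pCorrected = NA_real_,
            direction = "x_minus_y")
)

setValidity("RobustTestResult", function(object) {
  msg <- character(0)
  if (object@df <= 0) msg <- c(msg, "'df' must be > 0")
  if (is.na(object@pRaw) || object@pRaw < 0 || object@pRaw > 1)
    msg <- c(msg, "'pRaw' must be a probability")
  if (!is.na(object@pCorrected) &&
      (object@pCorrected < object@pRaw - 1e-12 || object@pCorrected > 1))
    msg <- c(msg, "'pCorrected' must lie in [pRaw, 1]")
  if (abs(object@xi) > 1)
    msg <- c(msg, "'|xi|' must not exceed 1")
  if (object@meanDifference != 0 && object@xi != 0 &&
      sign(object@xi) != sign(object@meanDifference))
    msg <- c(msg, "sign of 'xi' must match sign of 'meanDifference'")
  if (length(msg)) msg else TRUE
})

#' MannWhitneyResult: rank-sum test with Hodges-Lehmann shift
#'
#' @slot statistic numeric(1) the U statistic of the first sample.
#' @slot pValue numeric(1) two-sided p (exact when `exact` is TRUE, else
#'   normal approximation with tie correction and continuity correction).
#' @slot hlShift numeric(1) median of all pairwise differences `x_i - y_j`.
#' @slot ciLow,ciHigh numeric(1) confidence bounds for the shift obtained by
#'   inverting the test.
#' @slot conf numeric(1) nominal confidence level.
#' @slot exact logical(1) whether the exact null distribution was used.
#' @slot nx,ny integer(1) sample sizes.
#'
#' @seealso [mannWhitney()]
#' @export
setClass("MannWhitneyResult",
  representation(
    statistic = "numeric", pValue = "numeric",
    hlShift = "numeric", ciLow = "numeric", ciHigh = "numeric",
    conf = "numeric", exact = "logical", nx = "integer", ny = "integer"
  )
)

#' GroundTruth: planted effects of a synthetic cohort
#'
#' Label sets derived deterministically from a [SyntheticCohortSpec-class]:
#' areas with planted left dominance (`delta_p > 0`), right dominance
#' (`delta_p < 0`), and sided parcels carrying a handedness-group effect
#' (`g_p != 0`).
#'
#' @slot leftDominantAreas,rightDominantAreas character vectors of unsided
#'   area labels (`<area>_ROI`).
#' @slot groupAffectedParcels character vector of sided labels
#'   (`L_/R_<area>_ROI`).
#' @export
setClass("GroundTruth",
  representation(
    leftDominantAreas = "character",
    rightDominantAreas = "character",
    groupAffectedParcels = "character"
  )
)
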