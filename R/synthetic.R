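## Synthetic cohort generator: vertex maps with plantable hemispheric
## asymmetries and handedness-group effects, plus the ground truth needed to
## score recovery.

# Expand a per-area (or per-sided-parcel) effect specification: either a
# single number recycled, a full-length vector, or a named vector/list of
# nonzero entries over labels.
expandEffect <- function(value, labels, what) {
  p <- length(labels)
  if (is.null(value)) return(setNames(numeric(p), labels))
  if (is.list(value)) value <- unlist(value)
  if (is.null(names(value)) || !any(nzchar(names(value)))) {
    if (length(value) == 1L) return(setNames(rep(as.numeric(value), p), labels))
    if (length(value) == p) return(setNames(as.numeric(value), labels))
    stop("'", what, "' must be length 1, length ", p, ", or named")
  }
  bad <- setdiff(names(value), labels)
  if (length(bad))
    stop("unknown label(s) in '", what, "': ", paste(bad, collapse = ", "))
  out <- setNames(numeric(p), labels)
  out[names(value)] <- as.numeric(value)
  out
}

#' Specify a synthetic cohort
#'
#' Defaults describe the emulated study: two handedness groups of 70
#' subjects, 180 mirrored areas per hemisphere, 50 vertices per parcel,
#' mildly positive baseline activation on the z scale with unit vertex noise
#' and a smaller between-subject random effect. Asymmetries and group
#' effects default to zero and are planted explicitly.
#'
#' @param nPerGroup subjects per handedness group.
#' @param nParcelsPerHemi areas per hemisphere.
#' @param verticesPerParcel vertices per parcel.
#' @param baselineMu baseline vertex value (z scale).
#' @param parcelActivation per-area activation `a_p`: scalar, full vector,
#'   or named vector over area names (`P001`...).
#' @param lateralityDelta per-area left-minus-right asymmetry `delta_p`
#'   (positive = left-dominant), same forms as `parcelActivation`.
#' @param groupEffect per *sided* parcel effect added for left-handed
#'   subjects only; named over sided labels (`L_P001_ROI`, `R_P001_ROI`,
#'   ...), scalar, or full-length (`2 * nParcelsPerHemi`) vector.
#' @param subjectSd,vertexSd noise standard deviations.
#' @param contaminationProb,contaminationScale optional heavy-tailed noise:
#'   each vertex draws from `N(0, (contaminationScale * vertexSd)^2)` with
#'   probability `contaminationProb`.
#' @param contrast one of [peContrasts()].
#' @param seed master seed; per-subject seeds are derived from it by a
#'   counter-based scheme, so enlarging the cohort never changes earlier
#'   subjects.
#' @return A [SyntheticCohortSpec-class].
#' @examples
#' spec <- syntheticCohortSpec(nPerGroup = 3, nParcelsPerHemi = 4,
#'                             verticesPerParcel = 10,
#'                             lateralityDelta = c(P001 = 1.5), seed = 7)
#' @export
syntheticCohortSpec <- function(nPerGroup = 70L, nParcelsPerHemi = 180L,
                                verticesPerParcel = 50L, baselineMu = 0.5,
                                parcelActivation = 0, lateralityDelta = 0,
                                groupEffect = 0, subjectSd = 0.5,
                                vertexSd = 1, contaminationProb = 0,
                                contaminationScale = 3,
                                contrast = "STORY", seed = 1L) {
  areas <- defaultAreaNames(nParcelsPerHemi)
  sided <- c(sidedLabel(rep("left", nParcelsPerHemi), areas),
             sidedLabel(rep("right", nParcelsPerHemi), areas))
  new("SyntheticCohortSpec",
      nPerGroup = as.integer(nPerGroup),
      nParcelsPerHemi = as.integer(nParcelsPerHemi),
      verticesPerParcel = as.integer(verticesPerParcel),
      baselineMu = as.numeric(baselineMu),
      parcelActivation = expandEffect(parcelActivation, areas,
                                      "parcelActivation"),
      lateralityDelta = expandEffect(lateralityDelta, areas,
                                     "lateralityDelta"),
      groupEffect = expandEffect(groupEffect, sided, "groupEffect"),
      subjectSd = as.numeric(subjectSd), vertexSd = as.numeric(vertexSd),
      contaminationProb = as.numeric(contaminationProb),
      contaminationScale = as.numeric(contaminationScale),
      contrast = as.character(contrast), seed = as.integer(seed))
}

# Zero-padded generic area names P001..P180.
defaultAreaNames <- function(p) {
  sprintf("P%0*d", max(3L, nchar(as.character(p))), seq_len(p))
}

setMethod("show", "SyntheticCohortSpec", function(object) {
  cat("SyntheticCohortSpec:", 2L * object@nPerGroup, "subjects (",
      object@nPerGroup, "LH +", object@nPerGroup, "RH ),",
      object@nParcelsPerHemi, "areas/hemisphere x",
      object@verticesPerParcel, "vertices\n")
  cat(sprintf("  baseline %.3g, subjectSd %.3g, vertexSd %.3g, contrast %s, seed %d\n",
              object@baselineMu, object@subjectSd, object@vertexSd,
              object@contrast, object@seed))
  cat("  planted: ", sum(object@lateralityDelta != 0), " lateralized areas, ",
      sum(object@groupEffect != 0), " group-affected sided parcels\n",
      sep = "")
})

#' Build the mirrored parcellation of a synthetic spec
#'
#' Contiguous blocks of `verticesPerParcel` vertices per area, identical
#' layout on both hemispheres, labels `L_P###_ROI` / `R_P###_ROI`.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return A [Parcellation-class].
#' @export
makeParcellation <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  assign <- rep(seq_len(spec@nParcelsPerHemi), each = spec@verticesPerParcel)
  parcellation(defaultAreaNames(spec@nParcelsPerHemi), assign, assign)
}

#' Simulate one subject's vertex map
#'
#' Vertex value = `baselineMu + a_p + s * delta_p / 2 + 1[LH] * g_(sided
#' parcel) + u_subject + eps_vertex`, with `s = +1` on the left and `-1` on
#' the right hemisphere, `u ~ N(0, subjectSd^2)` drawn once, and `eps`
#' i.i.d. Gaussian vertex noise (optionally a contamination mixture).
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @param subject one row of a [subjectRecords()] data.frame.
#' @param seed integer seed for this subject's draws.
#' @return A [VertexScalarMap-class].
#' @export
simulateSubjectMap <- function(spec, subject, seed) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  p <- spec@nParcelsPerHemi
  assign <- rep(seq_len(p), each = spec@verticesPerParcel)
  nV <- length(assign)
  isLH <- identical(subject$handedness, "LH")
  gL <- spec@groupEffect[seq_len(p)]
  gR <- spec@groupEffect[p + seq_len(p)]
  muL <- spec@baselineMu + spec@parcelActivation + spec@lateralityDelta / 2 +
    if (isLH) gL else 0
  muR <- spec@baselineMu + spec@parcelActivation - spec@lateralityDelta / 2 +
    if (isLH) gR else 0
  set.seed(seed)
  u <- rnorm(1, 0, spec@subjectSd)
  drawNoise <- function() {
    eps <- rnorm(nV, 0, spec@vertexSd)
    if (spec@contaminationProb > 0) {
      hit <- runif(nV) < spec@contaminationProb
      if (any(hit))
        eps[hit] <- rnorm(sum(hit), 0,
                          spec@contaminationScale * spec@vertexSd)
    }
    eps
  }
  vl <- muL[assign] + u + drawNoise()
  vr <- muR[assign] + u + drawNoise()
  vertexScalarMap(subject$subject_id, spec@contrast, vl, vr)
}

#' Ground truth of a synthetic spec
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return A [GroundTruth-class]: unsided labels of left- and right-dominant
#'   areas (`delta_p > 0`, `delta_p < 0`) and sided labels of parcels with a
#'   handedness-group effect (`g_p != 0`).
#' @export
groundTruth <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  areas <- names(spec@lateralityDelta)
  new("GroundTruth",
      leftDominantAreas = sidedLabel(
        rep("unsided", sum(spec@lateralityDelta > 0)),
        areas[spec@lateralityDelta > 0]),
      rightDominantAreas = sidedLabel(
        rep("unsided", sum(spec@lateralityDelta < 0)),
        areas[spec@lateralityDelta < 0]),
      groupAffectedParcels = names(spec@groupEffect)[spec@groupEffect != 0])
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@leftDominantAreas), "left-dominant,",
      length(object@rightDominantAreas), "right-dominant areas;",
      length(object@groupAffectedParcels), "group-affected sided parcels\n")
})

#' Simulate a full cohort
#'
#' Generates `nPerGroup` left-handed subjects (EHI drawn uniformly from
#' -100..-40, the range observed in the emulated cohort) and `nPerGroup`
#' right-handed subjects (EHI +100), then one vertex map per subject using
#' counter-based per-subject seeds derived from the master seed.
#'
#' @param spec a [SyntheticCohortSpec-class].
#' @return A list with elements `subjects` (data.frame), `maps` (list of
#'   [VertexScalarMap-class], same order), and `truth`
#'   ([GroundTruth-class]).
#' @export
simulateCohort <- function(spec) {
  stopifnot(is(spec, "SyntheticCohortSpec"))
  validObject(spec)
  n <- spec@nPerGroup
  ids <- sprintf("S%04d", seq_len(2L * n))
  set.seed(deriveSeed(spec@seed, 0L))
  ehi <- c(-sample(40:100, n, replace = TRUE), rep(100L, n))
  subjects <- subjectRecords(ids, ehi)
  maps <- lapply(seq_len(2L * n), function(i) {
    simulateSubjectMap(spec, subjects[i, ], deriveSeed(spec@seed, i))
  })
  list(subjects = subjects, maps = maps, truth = groundTruth(spec))
}
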