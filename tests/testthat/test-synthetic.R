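# Synthetic cohort generator: determinism, construction, planted effects.

test_that("spec validation rejects impossible parameters", {
  expect_error(syntheticCohortSpec(nPerGroup = 0), "positive")
  expect_error(syntheticCohortSpec(vertexSd = 0), "vertexSd")
  expect_error(smallSpec(lateralityDelta = c(NOPE = 1)), "unknown label")
  expect_error(smallSpec(groupEffect = c(P001 = 1)), "unknown label")
  # group effects are sided
  s <- smallSpec(groupEffect = c(R_P001_ROI = 0.5))
  expect_equal(sum(s@groupEffect != 0), 1)
})

test_that("the generated parcellation has mirrored contiguous parcels", {
  spec <- syntheticCohortSpec(nPerGroup = 2, nParcelsPerHemi = 2,
                              verticesPerParcel = 3, seed = 1)
  parc <- makeParcellation(spec)
  expect_equal(nParcelsPerHemi(parc), 2)
  expect_equal(length(parcelAssignment(parc, "left")), 6)
  expect_equal(parcelAssignment(parc, "left"), rep(1:2, each = 3))
  expect_identical(parcelAssignment(parc, "left"),
                   parcelAssignment(parc, "right"))
  expect_equal(parcelLabels(parc),
               c("L_P001_ROI", "L_P002_ROI", "R_P001_ROI", "R_P002_ROI"))

  big <- syntheticCohortSpec(seed = 1)
  bigParc <- makeParcellation(big)
  expect_equal(nParcelsPerHemi(bigParc), 180)
  parsed <- parseRegionLabel(parcelLabels(bigParc))
  expect_equal(sum(parsed$side == "left"), 180)
  expect_setequal(parsed$area[parsed$side == "left"],
                  parsed$area[parsed$side == "right"])
})

test_that("subject maps realize the planted mean structure", {
  # no effects, vanishing noise: every vertex sits at the baseline
  quiet <- syntheticCohortSpec(nPerGroup = 1, nParcelsPerHemi = 2,
                               verticesPerParcel = 25, baselineMu = 1.7,
                               subjectSd = 0, vertexSd = 1e-9, seed = 4)
  subj <- subjectRecords("S1", 100)[1, ]
  m <- simulateSubjectMap(quiet, subj, 99)
  expect_equal(mapValues(m), rep(1.7, 100), tolerance = 1e-6)

  # planted asymmetry: left minus right parcel mean equals delta
  lat <- syntheticCohortSpec(nPerGroup = 1, nParcelsPerHemi = 2,
                             verticesPerParcel = 4000, subjectSd = 0,
                             vertexSd = 1, lateralityDelta = c(P002 = 1.5),
                             seed = 4)
  m <- simulateSubjectMap(lat, subj, 99)
  idx <- rep(1:2, each = 4000)
  d1 <- mean(mapValues(m, "left")[idx == 1]) -
    mean(mapValues(m, "right")[idx == 1])
  d2 <- mean(mapValues(m, "left")[idx == 2]) -
    mean(mapValues(m, "right")[idx == 2])
  expect_equal(d1, 0, tolerance = 0.1)
  expect_equal(d2, 1.5, tolerance = 0.1)

  # group effect applies to LH subjects on the specified sided parcel only
  ge <- syntheticCohortSpec(nPerGroup = 1, nParcelsPerHemi = 2,
                            verticesPerParcel = 4000, subjectSd = 0,
                            groupEffect = c(R_P001_ROI = 2), seed = 4)
  lh <- subjectRecords("L1", -100)[1, ]
  mLH <- simulateSubjectMap(ge, lh, 99)
  mRH <- simulateSubjectMap(ge, subj, 99)
  expect_equal(mean(mapValues(mLH, "right")[idx == 1]) -
                 mean(mapValues(mRH, "right")[idx == 1]), 2,
               tolerance = 0.1)
  expect_equal(mean(mapValues(mLH, "left")) - mean(mapValues(mRH, "left")),
               0, tolerance = 0.1)

  # fixed seed gives bit-identical maps
  expect_identical(mapValues(simulateSubjectMap(lat, subj, 123)),
                   mapValues(simulateSubjectMap(lat, subj, 123)))
})

test_that("cohorts are balanced, reproducible, and stable under growth", {
  spec <- smallSpec()
  co <- simulateCohort(spec)
  expect_equal(nrow(co$subjects), 10)
  expect_equal(sum(co$subjects$handedness == "LH"), 5)
  expect_true(all(co$subjects$ehi[co$subjects$handedness == "LH"] %in%
                    -(40:100)))
  expect_true(all(co$subjects$ehi[co$subjects$handedness == "RH"] == 100))

  co2 <- simulateCohort(spec)
  expect_identical(lapply(co$maps, mapValues), lapply(co2$maps, mapValues))

  # counter-based seed streams: enlarging the cohort leaves the first
  # subjects' maps untouched
  bigger <- smallSpec(nPerGroup = 8)
  co3 <- simulateCohort(bigger)
  for (i in 1:5)
    expect_identical(mapValues(co3$maps[[i]]), mapValues(co$maps[[i]]))
})

test_that("ground truth mirrors the planted effect sets", {
  spec <- smallSpec(lateralityDelta = c(P001 = 1, P003 = -0.5),
                    groupEffect = c(R_P002_ROI = 0.7))
  tr <- groundTruth(spec)
  expect_equal(tr@leftDominantAreas, "P001_ROI")
  expect_equal(tr@rightDominantAreas, "P003_ROI")
  expect_equal(tr@groupAffectedParcels, "R_P002_ROI")

  null <- smallSpec()
  trNull <- groundTruth(null)
  expect_length(trNull@leftDominantAreas, 0)
  expect_length(trNull@rightDominantAreas, 0)
  expect_length(trNull@groupAffectedParcels, 0)
})

test_that("with no planted asymmetry the paired statistic's sign is symmetric", {
  # Monte-Carlo exchangeability check: under delta = 0 the left and right
  # totals are exchangeable, so the sign of the hemispheric trimmed-mean
  # difference is a fair coin across cohorts.
  signs <- vapply(1:60, function(s) {
    spec <- syntheticCohortSpec(nPerGroup = 4, nParcelsPerHemi = 2,
                                verticesPerParcel = 15, seed = 1000 + s)
    co <- simulateCohort(spec)
    pe <- peCountTable(co$maps, makeParcellation(spec), co$subjects)
    sign(hemisphericComparison(pe, "STORY", "all")@meanDifference)
  }, numeric(1))
  nPos <- sum(signs > 0)
  nEff <- sum(signs != 0)
  # two-sided binomial check at the 0.1% level
  expect_gt(binom.test(nPos, nEff)$p.value, 0.001)
})

test_that("observed parcel-mean contrasts recover the planted deltas", {
  # slope of observed left-minus-right parcel means on planted delta
  p <- 12
  deltas <- seq(-1.5, 1.5, length.out = p)
  spec <- syntheticCohortSpec(nPerGroup = 50, nParcelsPerHemi = p,
                              verticesPerParcel = 500,
                              lateralityDelta = deltas, seed = 202)
  co <- simulateCohort(spec)
  idx <- rep(seq_len(p), each = 500)
  obs <- rowMeans(vapply(co$maps, function(m) {
    tapply(mapValues(m, "left"), idx, mean) -
      tapply(mapValues(m, "right"), idx, mean)
  }, numeric(p)))
  slope <- unname(coef(lm(obs ~ deltas))[2])
  expect_gt(slope, 0.95)
  expect_lt(slope, 1.05)
})

test_that("heavy-tailed contamination inflates tails but not the median", {
  spec <- syntheticCohortSpec(nPerGroup = 1, nParcelsPerHemi = 2,
                              verticesPerParcel = 20000, subjectSd = 0,
                              baselineMu = 0, contaminationProb = 0.1,
                              contaminationScale = 5, seed = 8)
  subj <- subjectRecords("S1", 100)[1, ]
  v <- mapValues(simulateSubjectMap(spec, subj, 55))
  clean <- mapValues(simulateSubjectMap(
    syntheticCohortSpec(nPerGroup = 1, nParcelsPerHemi = 2,
                        verticesPerParcel = 20000, subjectSd = 0,
                        baselineMu = 0, seed = 8), subj, 55))
  expect_gt(sd(v), sd(clean))
  expect_equal(median(v), 0, tolerance = 0.05)
})
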