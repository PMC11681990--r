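# peLaterality

Parcel-level hemispheric lateralization of task activation on cortical
surface maps, quantified by **positive-element (PE) counts** and analyzed
with robust trimmed-mean statistics.

## The problem and who this is for

Surface-based task fMRI yields, per subject and contrast, a statistical map
over two mirrored hemispheric meshes. A recurring question — how strongly
language activation lateralizes, and whether left- and right-handed groups
differ — needs an activation currency that is comparable across parcels and
robust to the heavy tails of real maps. This package implements such an
analysis for researchers working with parcellated surface statistics:

* A vertex is a **positive element** of a map iff its value is strictly
  positive *and* at or above the mean of that subject's whole-surface map
  (`value > 0 & value >= mean`; the threshold basis is configurable).
  Per-parcel PE counts and hemisphere totals are the unit of analysis.
* All location inference uses **20% trimmed means**: Yuen's paired test
  (hemispheric and per-area comparisons, statistic
  `T = (x̄_t − ȳ_t)/SE`, `SE² = (d_x + d_y − 2d_xy)/(h(h−1))`, `df = h−1`)
  and the Welch-type independent Yuen test (handedness-group comparisons),
  with winsorized variances and effective size `h = n − 2⌊γn⌋`.
* Effects are reported as the signed **explanatory measure of effect size
  ξ** (`ξ² = between-trimmed-mean variance / rescaled winsorized total
  variance`, capped at 1; 0.10/0.30/0.50 ≈ small/medium/large), and
  multiplicity is controlled per comparison family with
  **Benjamini–Hochberg FDR** (180 area tests or 360 sided-parcel tests).
* Subject covariates (age, accuracy, reaction time) are compared with an
  exact-capable **Mann–Whitney U** plus Hodges–Lehmann shift estimates.

Because the emulated study's subject data are access-restricted, the
package ships a **synthetic cohort generator** that plants known
asymmetries (`δ_p`, applied ±δ/2 per hemisphere), handedness-group effects,
subject random effects and vertex noise, so the entire pipeline is
validated by parameter recovery. PE count tables are
`SummarizedExperiment` objects (sided parcels × subject-contrast samples).

## Worked example

```r
library(peLaterality)

spec <- syntheticCohortSpec(nPerGroup = 20, nParcelsPerHemi = 6,
                            verticesPerParcel = 40,
                            lateralityDelta = c(P003 = 1.2), seed = 42)
cohort <- simulateCohort(spec)
pe <- peCountTable(cohort$maps, makeParcellation(spec), cohort$subjects)
pe
#> PECountTable: 12 sided parcels x 40 subject-contrast samples
#>   surface totals: median 238.5 PEs (range 155 - 250 )
#>   threshold basis: full_map

hemisphericComparison(pe, "STORY", "all")
#> Robust trimmed-mean test
#>   t = 9.2036, df = 23.00, p = 3.573e-09
#>   trimmed-mean difference (left_minus_right) = 17.1667  [13.3082, 21.0251]
#>   explanatory effect size xi = 0.929

summarizeSignificant(withinGroupParcelTests(pe, "STORY", "all"))
#>     region statistic df mean_difference   ci_low  ci_high            p
#> 1 P003_ROI  -23.0771 23         -17.125 -18.6601 -15.5899 2.090851e-17
#>    p_corrected         xi
#> 1 1.254511e-16 -0.9784473
```

Reading the output: planting a left-dominant asymmetry of 1.2 vertex-SD in
area `P003` produces a whole-hemisphere left excess of ~17 PEs per subject
(paired Yuen p ≈ 4e-09, ξ = 0.93, large). The per-area table is oriented
right − left (the published-table convention), so the planted area appears
with a *negative* mean difference and ξ ≈ −0.98, and it is the only area
surviving BH correction across the 6-area family.

A full run — simulate, extract PEs, analyze, report, with a manifest and
per-stage TSV artifacts — can be driven from a YAML config:

```r
runPipeline(system.file("extdata", "demo-config.yaml",
                        package = "peLaterality"),
            outdir = "demo-run")
```

or from a shell via the installed wrapper
`system.file("scripts", "pe-laterality", package = "peLaterality")`
(subcommands `simulate`, `extract-pe`, `analyze`, `report`, `run`).

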