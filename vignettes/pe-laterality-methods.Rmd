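---
title: "Methods: positive-element counting and robust lateralization inference"
author: "peLaterality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: positive-element counting and robust lateralization inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peLaterality)
```

## The problem

Language processing is lateralized: task activation on the cortical surface
is systematically stronger in one hemisphere, usually the left, and the
degree of asymmetry may differ between left- and right-handed people.
`peLaterality` quantifies this at the resolution of a mirrored cortical
parcellation (by default 180 areas per hemisphere, the granularity of the
multimodal parcellations used in surface-based fMRI) using a deliberately
simple activation currency: the **positive element (PE)**.

Given one subject's vertex-level statistical map (z scale, two hemispheric
meshes of equal vertex count), a vertex is a PE iff

* its value is strictly positive, and
* its value is at or above the mean of the map.

The per-parcel PE count is the number of such vertices inside the parcel;
hemisphere totals are the sums over each hemisphere's parcels. Counting
vertices rather than averaging intensities avoids arbitrary cluster-forming
thresholds, at the documented cost of ignoring intensity differences above
threshold.

### The threshold, precisely

The counting procedure first discards negative values and then applies a
threshold "at or above the mean". Two readings are defensible, and both are
implemented behind `thresholdBasis`:

* `"full_map"` (default): the mean is taken over **all** vertices of the
  subject's map, negatives included, and combined with the
  discard-negatives step as `value > 0 & value >= mean`. The effective
  threshold is therefore `max(0, mean)`.
* `"nonnegative_map"`: the mean of the nonnegative values only, i.e. the
  mean of the map after the discard step.

The default honours the description of the mean as being computed across
the entire brain surface. The threshold is always per subject x contrast
(each map's own mean), never pooled across a cohort, so PE counts are
invariant under positive rescaling of a map. Ties at the threshold count as
PEs ("equal to or above"), with exact floating-point comparison.

One consequence worth knowing: the threshold couples vertices through the
shared mean. Raising a single vertex raises the map mean by `d/N`, so the
raised vertex itself can only gain PE status (its own margin grows), and
vertices in *other* parcels can only lose it — but a sibling vertex inside
the same parcel can be pushed just below threshold, so a parcel's count is
not monotone in its own vertices' values. The test suite asserts the exact
per-vertex statement against brute-force recounts. The same coupling means
that planting a strong effect in a few parcels slightly depresses counts
everywhere else on that subject's map; in between-group designs this can
propagate planted effects into formally "unaffected" parcels. That is a
property of the counting rule, not a bug, and the recovery analyses score
only the planted parcels.

## Robust inference

PE counts are integer-valued, skewed, and occasionally extreme, so all
location comparisons use 20% trimmed means with winsorized variances
(`trim` is a package-wide parameter; `g = floor(trim * n)` observations are
removed from each tail, effective size `h = n - 2g`).

* **Paired design** (`yuenPaired`): statistic
  $T = (\bar x_t - \bar y_t)/SE$ with
  $SE^2 = (d_x + d_y - 2 d_{xy}) / (h(h-1))$, where $d_x, d_y, d_{xy}$ are
  winsorized sums of squares and aligned cross-products; $df = h - 1$.
* **Independent design** (`yuenIndependent`): Welch-type with
  $d_j = (n_j - 1)\,s^2_{w,j} / (h_j(h_j - 1))$,
  $T = (\bar x_{t1} - \bar x_{t2})/\sqrt{d_1 + d_2}$ and the
  Welch–Satterthwaite df analogue. At `trim = 0` both reduce exactly
  (to 1e-10 in the tests) to the classical paired t and Welch t tests.
* **Effect size** (`explanatoryEffectSize`): the explanatory measure
  $\xi$, with $\xi^2$ the ratio of the variance of the two group trimmed
  means (divisor 1) to the winsorized variance of the pooled data rescaled
  by the normal-consistency constant (division by 0.4121 at 20% trimming;
  1 at no trimming), capped at 1 and signed by the trimmed-mean
  difference. Bands 0.10 / 0.30 / 0.50 read as small / medium / large.
  Two choices here were genuinely open and are fixed deterministically:
  for unequal group sizes the pooled sample is the plain concatenation
  (no subsampling of the larger group), and for the paired design the same
  marginal formula is applied to the two margins — the dependence enters
  the test statistic, not this descriptive ratio. Note the ratio is a
  *descriptive* quantity: for two well-separated unit-variance groups of
  equal size its limit is about 0.91, not 1, and for unbalanced separated
  groups it can exceed 1, which is why the cap exists.
* **Interval summaries** (`trimmedMeanSummary`): SE
  $s_w / ((1 - 2\gamma)\sqrt n)$ and a symmetric t interval on
  $h - 1$ df (the df convention is not forced by the summary definition;
  $h-1$ matches the tests').
* **Demographics** (`mannWhitney`): U from midranks; exact subset-sum null
  distribution when $n_x n_y \le 400$ and there are no ties, otherwise the
  tie-corrected normal approximation with continuity correction; the
  location estimate is the Hodges–Lehmann median of pairwise differences
  with a CI from inverting the test at the U critical values.
* **Multiplicity** (`bhAdjust`): Benjamini–Hochberg step-up, applied per
  comparison family — the 180 within-group area tests or the 360
  between-group sided-parcel tests of one contrast x group, never pooled
  across contrasts.

## Comparison designs and sign conventions

Each design fixes its own orientation, recorded in the output:

| design | unit | test | positive means |
|---|---|---|---|
| `hemisphericComparison` | per-subject totals | paired | left > right (left dominance) |
| `withinGroupParcelTests` | area (unsided label) | paired, right − left | right-hemisphere dominance |
| `betweenGroupParcelTests` | sided parcel | independent, LH − RH | larger counts in left-handers |

The within-group orientation (right − left) follows the convention of the
published per-area tables even though the headline narrative emphasizes
left dominance; the global hemispheric comparison reports left − right.
Significant-result tables (`summarizeSignificant`) retain
`p_corrected <= alpha` — boundary inclusive — and order rows by descending
signed $\xi$ (positive block first, each block decreasing).

## The synthetic cohort generator

Restricted-access subject data cannot ship with a package, so validation is
by parameter recovery on synthetic cohorts
(`syntheticCohortSpec`, `simulateCohort`). A vertex value is

$$ v = \mu_0 + a_p + s\,\delta_p/2 + \mathbf 1[\mathrm{LH}]\,g_{p,s} + u + \varepsilon $$

with parcel activation $a_p$, left-minus-right asymmetry $\delta_p$
(applied $+\delta_p/2$ on the left, $-\delta_p/2$ on the right), a sided
group effect $g$ added for left-handed subjects only, a subject random
effect $u \sim N(0, \sigma_s^2)$ and i.i.d. vertex noise
$\varepsilon \sim N(0, \sigma_v^2)$, optionally contaminated by an
inflated-SD Gaussian component to exercise the robustness of the trimmed
statistics.

Defaults, chosen once to mirror the emulated study and held fixed: 70
subjects per handedness group (left-handers' EHI drawn from −100..−40,
right-handers at +100), 180 areas per hemisphere, 50 vertices per parcel,
baseline 0.5 on the z scale (mild positive task activation), vertex SD 1,
subject SD 0.5, no contamination. Per-subject seeds are derived from the
master seed by a counter-based mix, so enlarging a cohort never reshuffles
earlier subjects.

What the generator does **not** emulate: spatial autocorrelation on the
mesh, task design and hemodynamics, non-Gaussian tails of real z maps
(unless contamination is switched on), unequal parcel sizes, and medial-wall
gaps (the synthetic parcellation is a full partition). Passing recovery
tests therefore demonstrates correctness of the statistical machinery under
a clean generative model, not performance on real surface maps.

## Numerical and degenerate-input choices

* `g = floor(trim * n)`, the standard convention; only
  `trim` in {0, 0.2} is accepted by $\xi$ (the consistency constant is
  tabulated for those).
* A paired or independent test with zero SE returns statistic 0 and p = 1
  when the trimmed-mean difference is also zero (e.g. an all-zero parcel),
  and raises an error otherwise — silent certainty is never reported.
* $\xi$ with zero pooled winsorized variance errors unless the between
  term is also zero (then 0).
* Reals are serialized with 15 significant digits; round-trips through the
  TSV formats are tested to 1e-12. Vertex indices are 0-based in files,
  1-based in R; hemispheres are never concatenated into one index space.
* An EHI of exactly 0 has no handedness group and is rejected.

## Problem sizes used in the shipped checks

The package's own validation runs at the emulated study's scale where it
matters and smaller elsewhere: null calibration uses 5,000 replicates at
n = 70 per test; FDR control uses 200 all-null cohorts of 70 subjects x
180 areas; planted-effect recovery uses 20 cohorts of 140 subjects
(20 lateralized areas at $\delta = 1.5\sigma_v$, and 10 group-affected
right-hemisphere parcels at $g = 1.5\sigma_v$); estimator oracles use
1,000 random instances each. The acceptance script
(`scripts/acceptance.R`) re-runs the full pipeline at the 70 + 70 x 180 x
50 scale from a fresh seed and reports only quantities it computes in that
run.

## Known limitations

* PE counting discards intensity information above threshold; two parcels
  with equal counts may carry very different signal.
* The within-group $\xi$ for the paired design uses the marginal formula
  (see above); published per-area values could not disambiguate the
  variant, so treat cross-study comparisons of paired $\xi$ with care.
* The Mann–Whitney CI uses the Moses order-statistic construction; for
  heavily tied small samples it is conservative.
* No spatial statistics: parcels are exchangeable units, neighbourhood
  structure is ignored by design.
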