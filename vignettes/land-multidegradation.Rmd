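---
title: "Modelling land multi-degradation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling land multi-degradation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdi)
```

## The model

Agricultural land is rarely threatened by a single degradation process.
`lmdi` models the *co-occurrence* of twelve processes — water erosion
(WaE), wind erosion (WiE), soil organic carbon loss (SOCL), salinization
(SS), acidification (SA), compaction (SC), nutrient imbalance (SNI),
pesticide pollution (SPP), heavy-metal pollution (SPHM), vegetation
degradation (VD), groundwater decline (GD) and aridity (A) — on a common
equal-area raster (nominally 500 m cells).

Each process carries one documented *criticality rule* that maps its raw
metric to Critical (1) / Non-critical (0). The **Land Multi-degradation
Index** of a pixel is the number of processes critical there:

$$\mathrm{LMI}(x) \;=\; \sum_{k=1}^{12} \mathbf{1}\!\left[\,r_k(v_k(x))\,\right] \in \{0,\dots,12\},$$

interpreted through five classes — very low (1 process), low (2),
medium (3), high (4), very high (≥ 5) — with 0 meaning no degradation.
The binning is fixed; Jenks natural breaks (`natural_breaks()`, exact
dynamic programming) is provided only as the corroborating instrument it
was originally used as, never as the binning path.

### The rule registry

Thresholds are **data, not code** (`default_registry()`): every scalar
cut-off is listed with its comparison operator so the uncertainty stage
can perturb thresholds without touching classification logic.

| process | rule |
|---|---|
| WaE, WiE | erosion rate > 2 t ha⁻¹ yr⁻¹ |
| SOCL | Sen slope < −0.1 t C km⁻² yr⁻¹ and MK p ≤ 0.1 |
| SS | saline/sodic share > 50 % |
| SA | pH < 5.5 |
| SC | susceptibility class High or Very High (ordinal code > 3.5) |
| SNI | N surplus > 50 kg/ha, or NUE > 0.9, or (P > 50 mg/kg and positive budget), or (P < 25 mg/kg and negative budget) |
| SPP | risk score > 3 (High/Very High classes) |
| SPHM | any of As > 5, Cd > 1, Cr > 100, Co > 20, Pb > 60, Sb > 2, Ni > 50, Cu > 100, Hg > 0.5 mg/kg |
| VD | NDVI Sen slope < −0.001 yr⁻¹ and MK p ≤ 0.1 |
| GD | groundwater-table-depth Sen slope < −0.001 m yr⁻¹ and MK p ≤ 0.1 |
| A | aridity index P/PET in [0.03, 0.65) — dry sub-humid, semi-arid or arid; hyper-arid excluded |

Scalar comparisons printed as ">" or "<" are **strict**: a value exactly at
a cut-off is Non-critical. The two deliberate exceptions are non-strict by
nature: the Mann-Kendall significance level (p ≤ 0.1) and the lower dryland
bound (AI ≥ 0.03 keeps arid land critical). `boundary_stress_cases()`
generates inputs exactly at every strict threshold to pin the convention
down in tests.

Two ordinal layers need a note. Compaction susceptibility and pesticide
risk arrive as classes, not quantities. Pesticide risk has a documented
scalar form (High means risk score above 3), which the registry uses
directly. Compaction is carried as an ordinal code 1–5 (very low … very
high) with the scalar cut 3.5, so that "High and Very High critical" is
expressible as a perturbable threshold like every other rule. The lower
pesticide-risk class bins in `risk_score_to_class()` are a package
convention; they never affect criticality.

### Trend detection

SOCL, VD and GD criticality rests on pixel-wise monotone trends in annual
stacks: the Mann-Kendall statistic $S=\sum_{i<j}\mathrm{sign}(x_j-x_i)$
with the tie-corrected variance
$\mathrm{var}(S) = \big[n(n-1)(2n+5) - \sum_t t(t-1)(2t+5)\big]/18$,
a continuity-corrected normal deviate ($S \mp 1$), a two-sided p-value,
and Sen's slope (median of all pairwise slopes, with calendar-year
denominators so gaps widen the spacing rather than vanish). Numerical
choices, all surfaced as configuration:

* the normal approximation is used at every length handled here (the
  analysis windows are 10–21 years); an exact permutation oracle backs it
  in the tests for n ≤ 8, where the approximation is weakest;
* pixels with fewer than 70% of years present get nodata (`min_frac`);
  annual satellite/model series are near-complete, so the cut rarely binds;
* p ≤ 0.1 is applied non-strictly, matching its printed form.

## The synthetic world

No real rasters ship with the package; `gen_process_inputs()` generates
all twelve inputs *with known ground truth* so the pipeline can be tested
end-to-end. The generator's defaults are a stated world, chosen once:

* **64 × 64 cells of 500 m** on an abstract equal-area plane — the working
  resolution of the real analysis, at desk scale;
* **planted Critical fraction 0.20 per process, 0.25 for aridity** —
  drylands cover roughly a quarter of Europe's agricultural context, and
  one-in-five criticality keeps all six LMI classes populated without
  saturating any of them;
* **autocorrelation length 6 cells**, Gaussian-kernel smoothing of white
  noise: degradation is spatially coherent, not salt-and-pepper;
* **trend windows SOCL 15, NDVI 16, GTD 10 years** — the real analysis
  windows; planted declines are 5 × the slope cut-off with noise at 2% of
  the slope, so Mann-Kendall detection is certain and recovery tests are
  exact rather than probabilistic;
* **agricultural cover 70% of the domain, arable 40%** (CORINE-like codes:
  211–213 arable; 221–223, 231, 241–244 other agricultural; 311
  non-agricultural);
* **four Voronoi zones**, the last integrating only 9 of 12 layers
  (acidification, compaction, heavy metals withheld) — mirroring the
  countries reported with incomplete data;
* **margin 0.05**: raw values keep at least 5% of the threshold magnitude
  away from every cut-off, so binary recovery is never decided by floating
  point. `margin = 0.10` or more gives the "well-separated" scenario used
  in the separability-limit tests.

With `planted_class_proportions`, the generator instead plants *exact* LMI
class shares over the agricultural stratum (largest-remainder integer
allocation), which the end-to-end reproducibility test consumes.

What the generator does **not** emulate: the marginal distributions of real
European erosion/pollution data, cross-process correlation (each process's
field is independent), mixed native resolutions (everything is born on the
common grid; `align_to_template()` is exercised separately), and
geographic CRS subtleties (the plane is declared equal-area; areas are
pixel count × cell area). A green recovery test therefore establishes that
the rule registry, masking, summation and reporting are correct — not that
the package reproduces any real-world number.

## Uncertainty analysis

Thresholds are judgement calls; their effect is quantified in three steps.

1. **Perturbation** (`sample_thresholds()`): every scalar threshold t₀ is
   redrawn from Normal(t₀, |t₀|/10) — one-tenth of the threshold as
   standard deviation — independently per scalar and draw (reference
   20,000 draws; desk scale 2,000). Composites are perturbed per scalar:
   all four nutrient cut-offs, all nine metal limits, both AI bounds, and
   the slope and p cut-offs of each trend rule, each with its own |t₀|/10.
   A zero threshold (the P-budget sign) has zero sd and stays fixed, which
   is the stated law taken literally. No truncation is applied to
   sign-flippable thresholds (e.g. −0.001): also the stated law.
2. **Relabelling** (`simulate_lmi_labels()`): the stacked input matrix
   (one column per thresholded quantity, rows = sampled stratum pixels) is
   re-binarized under each draw; row sums re-bin to LMI classes, giving
   per-pixel label distributions and per-draw class areas.
3. **Classification model** (`fit_rf_uncertainty()`): a Random Forest
   (reference 1000 trees, 20 repetitions; desk scale 200 × 5) is trained
   on the original input values against perturbed labels — one draw per
   repetition, with a `target = "baseline"` switch, since the original
   description leaves the target ambiguous. It yields per-pixel class
   probabilities (vote shares), an out-of-bag error and impurity-based
   importances, the sensitivity ranking of the inputs.

The forest itself is implemented in compiled code in this package (Gini
CART on bootstrap samples, per-node feature subsampling, mtry = ⌊√p⌋,
terminal node size 1 — the standard classification defaults) because no
random-forest package is available in the target environment. It is
validated in the test suite against problems with known difficulty.

**Error ranges.** The class-area range construction is not fully specified
upstream, so `class_area_error_ranges()` computes and labels both: the
expected area under the RF probabilities, and the min–max envelope of
class areas across draws. The envelope includes the unperturbed baseline
tally as its zero-perturbation member: raw-value density generally differs
on the two sides of a cut-off, so perturbation shifts class areas
*asymmetrically* and a pure draw envelope can exclude the baseline —
incoherent for a report of the form "area ± error".

### A known limitation, kept visible

In the separability limit (sd → 0, labels deterministic, ≥ 10% data
margins) one might expect the forest to reach near-zero out-of-bag error.
It does not, and cannot at desk scale: the LMI class is a binned **sum of
12 independent indicators**, so the forest must represent a 12-dimensional
combinatorial count function. Measured on this package's validated forest,
OOB error is ~0.17–0.25 for 2,000–20,000 training rows regardless of mtry,
node size or tree count, while the same forest scores ~0.001 on linearly
separable 3-class data and ~0.01 on a 5-indicator sum. The corresponding
acceptance expectation (OOB ≤ 0.05) is asserted as specified and left
failing rather than weakened; the in-sample contracts (modal predicted
class = baseline for ≥ 99% of pixels, probabilities summing to 1, planted
importance ranking) all hold. Continental-scale applications of this same
construction report out-of-bag errors of the same order, consistent with
the count structure being the dominant source of difficulty.

## Reporting conventions

* Zones with fewer than 12 integrated layers are reported per zone but
  excluded from aggregate ("ALL") rows; both behaviours are visible in
  `zonal_stats()` output via the `incomplete` flag.
* Mean co-occurrence per zone is area-weighted and **includes class-0
  pixels** by default (they are agricultural land); `include_class0_in_mean`
  toggles the alternative reading.
* Combination ranking is by km² (identical to pixel counts on a uniform
  grid); ties break by ascending canonical bitset, and modal display
  coarsening (`coarsen_display()`, 500 m → 5 km) breaks block ties by the
  lowest bitset. Coarsening is display-only: every table is computed at
  native resolution.
* Resampling: nearest-neighbour for categorical layers (enforced),
  bilinear for continuous fields. The working CRS and resampling kernels
  are configuration, not inference: no single convention is standard
  across the source datasets this kind of analysis consumes.
* Raster files are uncompressed GeoTIFF with ModelPixelScale/ModelTiepoint
  georeferencing and the GDAL nodata tag, written and read by the
  package's own minimal codec (no raster library exists in the target
  environment); masks use nodata 255.

## What a green suite establishes

The unit and acceptance tests establish: bit-exact raster round-trips;
rule recovery of planted masks for all twelve processes including the
composites; strict-inequality boundary behaviour; Mann-Kendall/Sen
agreement with exact permutation oracles, type-I control and planted-slope
power; exact area conservation and threshold monotonicity; combination
tables equal to exhaustive tallies; threshold-draw laws and label-collapse
at sd = 0; and byte-identical end-to-end reruns. They do not establish
agreement with any published continental statistic — that requires the
original twelve rasters, which are outside this package's scope.
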