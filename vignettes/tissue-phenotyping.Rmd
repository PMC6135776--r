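---
title: "Tissue phenotyping from cell-network connection frequencies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue phenotyping from cell-network connection frequencies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenotile)
```

## The problem and the model

Colorectal tumors with the same clinical stage can behave very differently,
and part of that difference is written in the spatial organisation of the
tumor microenvironment: how malignant epithelial cells, inflammatory cells,
spindle-shaped cells (fibroblasts, smooth muscle) and necrotic debris are
arranged relative to one another. `phenotile` quantifies that organisation
from a *cell map* — the list of cell centroids and types that a cell
detection/classification model produces from a whole-slide image — and
relates it to distant-metastasis outcomes.

The local-architecture summary works in three steps:

1. **Tiling.** The slide is split into non-overlapping 200 µm × 200 µm
   square tiles (half-open intervals, so every cell belongs to exactly one
   tile). 200 µm is within the range of effective intercellular
   communication, which motivates treating a tile as one "locale".
2. **Cell network.** The cells of a tile are joined by their Delaunay
   triangulation, so an edge represents a pair of neighboring cells. Edges
   are never drawn between tiles: each tile is triangulated on its own.
3. **Connection frequencies.** With 4 cell classes there are 10 unordered
   pairs of endpoint types. A tile is summarised by the 10-vector
   *h* of edge-type proportions — a point on the simplex whenever the tile
   has any edge.

Tiles from all slides of a cohort are then pooled and clustered with
**k-medoids under the chi-squared distance**

$$d(h, m) = \sum_k \frac{(h_k - m_k)^2}{h_k + m_k},$$

a histogram dissimilarity bounded by 2 on the simplex. Medoids are
initialised uniformly at random and the partition/update iteration runs to
a local optimum; the whole procedure is restarted 100 times and the
replicate with the smallest total distance is kept. Every tile is then
labeled by its nearest medoid — its *tissue phenotype*. With the data this
package targets, the phenotypes correspond to smooth muscle, inflammation,
tumor-stroma interface, tumor, stroma and necrosis;
`name_phenotypes()` attaches those names heuristically from the dominant
connections of each medoid, purely as a cosmetic aid.

**Choosing the number of phenotypes.** For each candidate k, two
diagnostics are computed: the minimum pairwise chi-squared distance among
the medoids (phenotypes must stay distinct; below 0.2 is undesirable) and
the maximum Spearman correlation among the per-case phenotype-ratio
features the model induces (features must not be redundant; above 0.8 is
undesirable). The selected k is the largest value satisfying both. The
correlation is taken *signed*: phenotype ratios are compositional (they sum
to roughly 1 per case), so strong negative correlations are a structural
fact of ratios rather than evidence of redundancy — taking absolute values
would make k = 2 inadmissible always, since its two ratios are perfectly
anticorrelated by construction.

## Per-case features

Each case is reduced to a feature vector:

* **CF phenotype ratios** — area of each connection-frequency phenotype
  over total tissue area. With an appearance (AP) mask the numerator counts
  the tissue pixels of the mask inside the tiles of that phenotype, and the
  denominator is the mask's tissue area, where *tissue* excludes normal
  mucosa, fat and non-tissue background. Without a mask, tile counts over
  phenotyped tiles are used and the ratios sum to exactly 1.
* **AP ratios** — smooth-muscle and inflammation class areas over tissue
  area of the 9-class appearance mask.
* **Stroma-tumor ratio** `stroma / (stroma + tumor)` and
  **necrosis-tumor ratio** `necrosis / (necrosis + tumor)` on mask class
  areas, each `NA` when its denominator is empty (the case row is kept).
* **Morisita index** — the spatial coexistence of inflammatory and
  malignant cells. The package implements the Morisita–Horn overlap of
  quadrat counts, with quadrats equal to the 200 µm tile grid:
  `MH = 2 Σ x_q y_q / ((Σx_q²/X² + Σy_q²/Y²) X Y)`, in [0, 1]. The choice
  of the Morisita–Horn variant and of tile-aligned quadrats is a design
  decision of this package: the colocalization literature this statistic
  comes from uses the Morisita–Horn form, but other variants (and other
  quadrat sizes) exist, and results can depend on the choice.

## Prognostic statistics

* **Association tests**: Mann–Whitney rank-sum against binary clinical
  groupings; strength reported as `r² = Z²/N`, with Z the tie- and
  continuity-corrected normal-approximation statistic. Exhaustive
  enumeration shows the approximation tracks the exact permutation p-value
  to within 0.02 for untied groups of 8, but deviates substantially (up to
  ~0.13) for heavily tied tiny samples — the exact p from
  `stats::wilcox.test` is reported whenever it is available.
* **Logistic effects** on 5-year metastasis: the reported quantity is the
  interquartile odds-ratio factor `exp(β (Q3 − Q1))`, i.e. the change in
  odds when the feature moves from its 1st to its 3rd quartile, with a Wald
  CI on the same scale and a likelihood-ratio p-value for dropping the
  feature. Univariate AUC is the rank AUC of the feature itself;
  multivariate AUC is the model's.
* **Cox effects** on distant-metastasis-free survival, scaled the same
  way; Rao's score test univariately (equal to the log-rank test for a
  single binary covariate — the package tests this identity numerically to
  1e-6) and the Wald test per coefficient in adjusted models.
* **Bootstrap AUC**: Harrell-style optimism correction — apparent Somers'
  Dxy minus the mean over 100 resamples of (Dxy on the resample − Dxy of
  the refitted model on the original data), mapped to AUC = (Dxy + 1)/2.
  The optimism estimate is itself noisy: at modest n it can come out
  slightly negative, so the corrected AUC is not forced below the apparent
  one.
* **Survival stratification**: candidate cutoffs are the observed feature
  values inside the inner 10–90% quantile window (the window is
  configurable; the restriction keeps both groups populated). The cutoff
  with minimum log-rank p is reported with Altman's correction
  `P_cor = −1.63 P_min (1 + 2.35 ln P_min)`, valid for `P_min < 0.1` and
  clipped to `[P_min, 1]`; outside that range the corrected value is `NA`
  rather than an extrapolation.
* **Multiple imputation**: missing values are completed `m = 100` times
  (configurable; tests use 3–5): continuous columns by predictive mean
  matching with a posterior draw of the regression coefficients and a
  5-donor pool, two-level categorical columns by a fitted logistic draw,
  others by observed-proportion draws. Estimates are pooled by Rubin's
  rules (total variance `W + (1 + 1/m) B`, t reference with Rubin's
  degrees of freedom); for rank tests the median p and median r² across
  imputations are reported instead.
* Adjusted analyses default to differentiation, histological type and T
  stage as adjusters (plus the cohort indicator where both institutes
  contribute to the outcome); well- and moderately-differentiated tumors
  are never distinguished.

## What the synthetic generators emulate

The package ships generators so that every stage can be exercised without
patient data; their defaults define the study conditions used by the test
suite.

**Archetypes.** Six archetype profiles stand in for the six tissue
phenotypes. Each is defined by a 4-component cell mixture; its target
connection-frequency vector follows from the closed form for independent
type marks (`P(edge joins i,j) = 2 p_i p_j`, `p_i²` on the diagonal), which
makes planted truths analytically available. The default mixtures give
pairwise chi-squared separations ≥ 0.6 — comfortably above the 0.2
distinctness threshold, so the planted k is recoverable. Frequency vectors
are drawn from a Dirichlet with mean at the target and concentration 150,
giving within-cluster spread around 0.1 in chi-squared distance; this
"moderate tightness" was fixed once, at design time, as a plausible level
of tile-to-tile variability.

**Slides.** Cells are placed by a homogeneous Poisson process per
rectangular region (densities of 100–300 cells per 200 µm tile depending
on archetype) with independent type marks, and masks are rasterised at
2.2 µm/pixel by pixel-center containment. Real tiles are *not* homogeneous
Poisson — nuclei exclude one another, cells cluster, and boundaries between
tissue types are gradual — so passing recovery tests demonstrates that the
pipeline's inference machinery is correct under its own assumptions, not
that real slides are this clean. The generators also render no pixel-level
H&E appearance and no scanner artefacts.

**Cohorts.** Clinical covariates are drawn with marginals resembling a
two-institute colorectal series; the binary 5-year metastasis outcome
follows a logistic model and survival an exponential proportional-hazards
model with administrative censoring at 5 years. Planted coefficients are
interpreted *per interquartile range* of the realised feature, so the
analysis stage's interquartile effect factors are directly comparable to
`exp(β)`. Missingness is completely at random — the simplest mechanism
compatible with the imputation stage; informative missingness is out of
scope.

## Numerical choices and edge cases

* Tiles with fewer than `min_cells = 5` cells (or no edges) are flagged
  *unphenotyped* and excluded from clustering: frequency vectors from a
  handful of edges are too unstable. The flagged tiles stay in the tile
  table.
* Degenerate tiles: one cell gives no edges; two cells one edge; three or
  more collinear cells a consecutive-neighbor path — the natural 1-D limit
  of the triangulation. Exactly coincident coordinates are merged (first
  record's type kept) with a warning, since a triangulation needs distinct
  sites. Cocircular ties fall to the geometry backend's deterministic
  resolution; the test fixtures avoid exact cocircularity.
* Assignment ties (a vector equidistant from two medoids) go to the lower
  medoid index; k-medoids cost never increases across iterations, and the
  all-subset initialisation option reproduces the exhaustive optimum on
  small instances, which the tests verify.
* Zero denominators (no tissue, no tumor pixels, an empty cell population
  in the Morisita index, no admissible cutoff) yield `NA` or an explicit
  error, never a silent 0.
* All randomness flows from explicit integer seeds through private RNG
  streams that leave the caller's `.Random.seed` untouched; identical
  seeds give byte-identical outputs.

## Scale of the shipped checks

The test-suite simulations are sized for minutes, not hours: planted
clustering recovery uses 600 tiles (6 archetypes × 100), geometry and
clustering oracles use hundreds of instances of ≤ 8 points, effect-recovery
uses cohorts of 2 000 with coverage sweeps of 100 replicates at n = 400,
and the end-to-end pipeline demonstration uses 150 cases of 3 × 3 tiles.
These sizes were chosen so the planted effects dominate Monte-Carlo noise
by a comfortable margin while keeping runs quick.

## Known limitations

* Delaunay connectivity is a proxy for interaction; no edge-length cutoff
  is applied within tiles, so rare long edges across cell-sparse regions
  count like any other connection.
* The phenotype model is a hard partition; mixed tiles (e.g. exactly at a
  tumor-stroma boundary) are assigned to a single phenotype.
* The correlation criterion for k uses per-case phenotype ratios in
  maskless (tile-count) form during selection, which treats all tiles as
  equal-area; with masks the final features reweight by tissue pixels.
* The imputation model is linear/logistic in the complete covariates —
  adequate for the cohort tables this package targets, far from a general
  `mice` replacement.
* Reported clinical effect estimates from any real cohort depend on that
  cohort's data; the package's tests certify parameter recovery under the
  synthetic generators, not any published clinical number.
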