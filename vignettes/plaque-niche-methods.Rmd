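---
title: "Methods: amyloid-niche analysis on spot-based spatial transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: amyloid-niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
conventions behind `plaqniche`. The package analyses gene expression
around amyloid-beta (Aβ) deposits on spot-based spatial transcriptomics
arrays (Visium-style: ~55 µm capture spots on a 100 µm hexagonal pitch,
each containing roughly 1–10 cells), and ships a synthetic-data generator
with known ground truth so that every step can be validated end to end.

## Image domain: from segmented amyloid to a decayed density field

Input rasters are 8-bit single-channel images of segmented Aβ (and IBA1)
signal with a known µm-per-pixel scale. `binarize_and_clean()` thresholds
strictly above a configurable 0–255 cutoff, optionally median-despeckles,
applies a configurable number of morphological closing rounds with a
1-px-radius (3×3, 8-connected) structuring element, and removes
8-connected components whose physical area falls outside a configured
µm² range. Area thresholds are specified in µm² and converted by the
squared pixel size, so cleaning behaves identically across resolutions.

`expand_with_decay()` turns the binary mask into the density field the
niche definition consumes. The source is held at 255; beyond the
boundary, intensity steps down once per 20 µm band out to a 100 µm halo
and is zero after that. Distances are exact Euclidean distance-transform
values on pixel centers, with d = 0 inside the mask. The magnitude of
the per-band decrement is a design choice (the construction fixes only
the halo and band widths): we use a linear decrement, band
k ∈ {1..5} receiving ⌊255·(1 − k/6)⌋, i.e. 212, 170, 127, 85, 42. The
rationale: with the spot threshold of 183 on the same 0–255 scale, a
spot classifies as Aβ-rich when its capture disc is dominated by source
signal or the innermost band — "rich" remains synonymous with
"on or immediately around a plaque". Rounding is downward so the band
sequence is strictly decreasing.

Vascular (CAA-like) amyloid arrives as a separate label raster (from a
classifier or manual annotation — training one is out of scope);
`partition_vascular()` dilates the labels twice (1-px disc per round)
and splits the amyloid mask into vascular and cortical components that
exactly partition it. `area_coverage()` and `colocalization_fraction()`
are plain pixel-count ratios and are translation-invariant.

## Spot domain: rich spots, hex neighbors, niches

`spot_signal()` averages the density field over each spot's 55 µm
capture disc (pixel centers within the radius). The mean was chosen as
the aggregator because it makes the 0–255 spot intensity directly
comparable with the raster scale; a max aggregation can be emulated by
thresholding the raster first. `classify_rich()` uses a strict
inequality at the default threshold of 183 — a spot at exactly 183 is
not rich.

Neighbor order is **hex graph distance on array coordinates**, not
Euclidean distance: the grid stores odd-r offset coordinates (odd rows
shifted +½ column), converted to axial coordinates for the distance
computation. At 100 µm pitch, first-order neighbors sit at exactly
100 µm and second-order neighbors at √3·100 ≈ 173 µm or 200 µm, so the
order-2 hex ball realizes an approximate 200 µm radius exactly — the
19-spot niche (1 + 6 + 12) around an isolated rich spot.

`assemble_niche()` applies the exclusions before anything else: CAA
spots and their first-order neighbors, plus spots with unreliable
staining, are excluded and can never be rich or neighbors (an excluded
rich-intensity spot also stops seeding a niche). Neighbors are
restricted to the allowed regions (gray and white matter by default).
The output classes `{rich, neighbor, outside, excluded}` partition the
grid, and re-assembling from the output's rich set is idempotent.

Cell-type-enriched spots (`enriched_spots()`) are called per sample. In
top-quantile mode the cut is the empirical (1 − q) quantile within each
sample × region, with boundary ties all included — ties must not
silently drop spots, so the rule can select more than ⌈q·n⌉. In z-score
mode the cut is mean + z·sd over the sample's allowed-region spots
pooled; when the sd is zero nothing is selected. The default rule table
(`default_enrichment_rules()`) encodes the region-restricted
top-1/5/10/30/50% profiles per cell type, excludes layer I for atlas
cell types, and uses the 3-sd rule for immunization microglia clusters.

`nuclei_near_plaques()` bins nuclei by exact distance to the nearest
amyloid pixel with a strict `< 20 µm` near bin (a nucleus at exactly
20 µm is far) and tests type-by-bin association with a chi-square test.

## Differential expression

**Balanced downsampling** (`balance_downsample()`) enforces three caps
per comparison: no sample above 50% of its group, groups within 3-fold
of each other, and at most 3,000 units per group. The share cap is
enforced by iteratively trimming the largest sample to
⌊0.5 · current group total⌋ — the floor makes the iteration reach its
fixed point (e.g. a 900/100 group converges to 100/100); with a ceiling
the iteration can stall above 50% on odd totals. Because the group- and
fold-caps subsample at random and can nudge a share back above 50%, the
three steps repeat until all constraints hold; every pass strictly
shrinks the table, so termination is guaranteed. Single-sample groups
are exempt from the share cap, which they can never satisfy.

**Gene filtering** defines "expressed" as `count > 0` (the construction
leaves this open; detection is the only scale-free choice available
before normalization). Prefix exclusions (RPS/RPL/MT/HB) are literal,
case-sensitive prefix matches on the feature symbol — `MTOR` is
excluded alongside `MT-CO1`, faithfully to the stated rule.

**Pseudobulk route** (`pseudobulk_nb_test()`): raw counts are summed by
donor and passed to DESeq2 (Wald test, `fitType = "local"`,
`independentFiltering = FALSE`); we additionally disable the Cook's
outlier NA-ing so that every filtered gene receives a p-value.
Continuous covariates are standardized across donors. Fold changes are
unshrunk (effect-size shrinkage is a named external method and the
significance rule — BH-adjusted p < 0.05 and |LFC| ≥ log2 1.5 — does
not depend on it).

**Hurdle route** (`hurdle_test()`): per gene, a logistic model of
detection and a Gaussian model of expression among detected units are
each compared with their group-free nulls by likelihood-ratio tests;
the combined statistic sums the two χ² with summed df. An inestimable
component (all or no units detected; too few detected units) contributes
0 with 0 df. The log2 fold change is the difference of group means of
normalized expression divided by log 2, independent of the model fits.
Two deviations from the mixed-model hurdle it emulates are deliberate:
sample id is fitted as a fixed covariate rather than a random effect
(conservative for balanced designs, dependency-light, and only
applicable to within-donor contrasts — for donor-level group labels the
sample term is aliased with the group and must be omitted), and
normalization is `log1p` of counts scaled to the median library size
rather than a regularized variance-stabilizing transform. All
calibration and recovery tests are run on this normalization.

One statistical subtlety the synthetic cohort exposes: the cellular
detection rate (CDR) covariate is computed from the counts, so when
strong group-responsive programs are present, CDR sits downstream of
both the group and the library size — a collider. Conditioning on it is
standard practice and costs little in the planted scenarios, but type-I
calibration is therefore assessed on a planted-null cohort (all planted
LFCs zero), where CDR is clean of group signal.

**Protein route** (`protein_nb_test()`): per protein, an NB GLM (Poisson
fallback on non-convergence) of isotype-normalized counts on group plus
covariates; the reported fold change is the log2 ratio of group means
with a pseudocount of 1, with significance at adjusted p < 0.05 and
|LFC| > log2 1.5.

**Markers** (`find_markers()`): one-versus-rest Wilcoxon rank-sum per
cluster on genes strictly above 25% in-cluster detection, BH within
cluster, positive markers only by default. The profile used for
rich-cluster contrasts (detection 10%, both signs, |LFC| > log2 1.5) is
available through the same arguments.

## Trajectories

`fit_density_trajectories()` fits each gene with local-linear LOESS
(degree 1, tricube weights, no robustness iterations,
`surface = "direct"` so predictions are exact rather than interpolated)
at span 0.75 against spot amyloid density, and evaluates on 100 evenly
spaced density values over the observed range. Degree 1 is a deliberate
choice documented here because R's `loess()` defaults to degree 2;
local-linear fits reproduce global lines exactly and are the
conventional reading of "LOESS regression of span 0.75" in trajectory
analyses. Standardization is per gene across the prediction grid
("within each group" is read as per-gene z-scoring inside each group's
fit — the pooled alternative would let high-variance genes dominate the
clustering metric); zero-variance genes map to the all-zero row.
`cluster_trajectories()` uses complete-linkage hierarchical clustering
on Euclidean distances (the referenced routine's default linkage), with
k supplied by the analyst — reported cluster counts in comparable
analyses are outcomes of inspection, not of a stated selection rule —
and labels renumbered by descending cluster size.

## Ranking

Signed probabilistic fold change is `(−log₁₀ adj p) · LFC` with the
p-value floored at 1e-300. The log base is a reporting convention:
percentile ranks are invariant under any strictly monotone transform of
the p-value term, which the suite verifies by recomputing with natural
logs. Percentiles are `100 · rank/n` with ties averaged; combination
averages the two tables' percentiles over their gene intersection
(genes missing from one table are excluded, not imputed — an average
with a missing rank is undefined). Divergence is the PFC difference,
with opposite-sign pairs ranked above same-sign pairs of equal
magnitude.

`preranked_enrichment()` computes the weighted Kolmogorov–Smirnov
running-sum score (weight exponent 1) and a gene-permutation null
(random same-size sets), matching the preranked setting of the method
it emulates; NES divides the ES by the mean |null ES| of matching sign,
and the two-sided p uses same-sign tail counts with +1 smoothing. The
installed reference implementation is used in the test suite as an
independent cross-check of the ES, never as the implementation.

`adjusted_spearman()` rank-transforms everything, residualizes the x-
and y-ranks on the covariate ranks, and reports the Pearson correlation
of residuals with n − 2 − c degrees of freedom.

## The synthetic cohort: what it emulates and what it does not

The generator is the package's ground-truth instrument; every default
is an artifact choice, stated here once and not tuned afterwards.

* **Geometry** — per donor, a hex grid of 2,000 spots (100 µm pitch,
  55 µm spots) and an independent plaque field: Poisson plaque count at
  15/mm², log-normal radii (median 25 µm, σ_log 0.35), 15% of plaques
  relocated onto synthetic vessel polylines and labeled vascular.
  These magnitudes are typical of AD cortical plaque densities and
  sizes.
* **Recruitment** — myeloid somata placed with probability 0.6 within
  one radius of a plaque boundary and 0.05 elsewhere; per-spot
  recruitment excess decays as exp(−d/50 µm). Abundance tables are
  Dirichlet draws scaled by a 1 + Poisson(5) total-cells draw, with the
  microglia concentration multiplied by (1 + boost · excess).
* **Expression** — counts are NB(µ = L_s · p_g · 2^eff, θ = 2) with
  log-normal spot library sizes (median 5,000, σ_log 0.3) and a
  log-normal relative-abundance gene profile over a 2,000-gene panel.
  Planted programs: 50 niche genes with LFC decaying from a peak of 2
  at the plaque boundary with a 50 µm scale, and 100 group genes at
  |LFC| = 1.5 (half up, half down) in 6 immunized vs 6 control donors.
* **Covariates** — donor sex, age ~ N(80, 7), gDNA% ~ U(1, 10) are
  noise variables; CDR is computed from the counts.

Not emulated: staining artifacts and lipofuscin, raw reads and UMI
collapsing, segmentation error, the deconvolution model's posterior
(abundances are consumed, not estimated), donor-level expression random
effects beyond library size, and spatial autocorrelation of expression
beyond the plaque-distance effect. Passing tests on this cohort
demonstrate that the procedures recover what they are defined to
recover under their own assumptions; they do not certify performance on
real tissue, where those omitted features are the hard part.

## Problem sizes and numerical conventions

The validation suite runs the DE calibration and recovery checks at the
cohort's native scale (12 donors × 2,000 spots × 2,000 genes), which
keeps each check in the tens of seconds on a single core; raster checks
use 1 µm/px fields of a few hundred pixels, where the banded expansion
is exact. Ties: quantile cuts include boundary ties; rank percentiles
average ties; cluster-label renumbering breaks size ties by first
occurrence. Degenerate inputs follow the conventions above (empty masks
give empty/zero outputs; zero-variance genes give zero rows; sd = 0
z-rules select nothing; all-detected genes drop the logistic component).
Determinism: every stochastic function takes an explicit seed and runs
under a locally scoped RNG, so identical seeds give identical results
without touching the caller's RNG state.
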