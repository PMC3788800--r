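---
title: "Deductive migratory-concentration models: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deductive migratory-concentration models: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopover)
```

## The model

A deductive habitat-suitability model encodes literature and expert
knowledge directly as map algebra, rather than fitting coefficients to
occurrence data. For one bird group, the migratory importance score of cell
$c$ is

$$\mathrm{MIS}_c = \mathrm{norm}\Big(\sum_{i=1}^{n} w_i\,
  \mathrm{norm}\big(f_{ci} \prod_j m_{ij}\big)\Big),$$

with factors $f_{ci} \in [0,1]$ (0 = no importance, 0.25 low, 0.5 medium,
1 high), multiplicative modifiers $m_{ij} \in [0,2]$ (0 removes a factor,
1 is neutral, 2 doubles it), and positive weights $w_i$.
$\mathrm{norm}(\cdot)$ divides by the maximum unmasked cell, so each
modified factor carries equal relative importance before weighting and the
final surface spans $[0,1]$. Two consequences are worth keeping in mind:
the model is invariant to rescaling all weights by a common constant, and
an all-zero term (which drop-one partial models can produce) is passed
through as zeros rather than raising an error — the sensitivity analysis
depends on that.

The four canonical group specifications are returned by `canned_spec()`:
wetland birds (5 terms, wetland density weighted 3), riparian birds
(2 terms, streams weighted 2), raptors (4 unweighted terms) and sparse
grassland birds (2 unweighted terms). `migration_model()` evaluates a
specification against a `layer_stack` and returns a classed object with
`print`, `summary`, `coef`, `plot`, `predict` and `simulate` methods.
`residuals` is deliberately absent: nothing is fitted, so there is no
residual in the statistical sense.

## Factor and modifier conventions

Published class tables leave interval closures and functional forms
implicit; the conventions fixed here are:

* **Class boundaries are closed on the left.** Elevation: $<2438$ m
  $\to 1$, $[2438, 2743)$ m $\to 0.5$, $\ge 2743$ m $\to 0.1$. River
  proximity (to streams of order $\ge 3$): $<5$ km $\to 2$, $[5, 10)$ km
  $\to 1.5$, $\ge 10$ km $\to 1$. Wetland size: $<5$ ha $\to 0$,
  $[5,15]$ ha $\to 0.5$, $>15$ ha $\to 1$.
* **Wetland density** counts wetland representative points (polygon
  centroids) inside a 5-km circular window and divides by the window area,
  giving wetlands/km²; centroid counting avoids double-counting polygons
  that span cells. Importance is 0 below 2/km², ramps linearly from 0.25
  at 2/km² to 1 at 28/km², and clamps at 1 above (only the two ramp
  anchors are published; the clamp is the conservative completion).
  Sub-5-ha wetlands count toward density even though they carry no size
  value.
* **Inverse-distance-squared decay** (riparian and raptor streams): the
  published rule names the family, not the formula. The implementation
  keeps the source value $v$ at the source cell and assigns
  $v \cdot \min(1, (\mathrm{cellsize}/d)^2)$ at center-to-center distance
  $d \le 500$ m, 0 beyond; $v$ is the value of the *nearest* source, with
  ties resolved toward the larger value. This keeps "some value" within
  500 m without a hard buffer.
* **Take-off/approach buffer**: every cell within 1 km of a valued wetland
  or stream carries that source's value; overlapping buffers max-combine.
  Buffers extend around any wetland with a nonzero size value (0.5 or 1).
* **Topographic position (TPI)**: elevation minus its circular focal mean,
  standardized by the standard deviation of that difference, at two window
  sizes interpreted as *diameters* of 20 and 50 cells (radii 10 and 25);
  cells with standardized TPI $> 1$ in either window are ridge-like
  landforms. The published tool names landforms, not thresholds; the
  $>1\sigma$ rule is the common landform-classification default, and the
  diameter reading keeps the operation defined on the 100-cell landscapes
  used throughout. Relief-free surfaces (numerically: TPI spread below
  $10^{-9}$ of the relief) are treated as flat.
* **Updrafts**: aspect (downslope azimuth from the elevation gradient;
  flat cells flagged) and prevailing wind are both classified into 8
  compass sectors; identical sectors score 1, circularly adjacent sectors
  0.75, anything else 0. The wind grid is treated as a category layer;
  whether it encodes "blowing from" or "blowing toward" does not change
  the equality rule, only its interpretation, and the synthetic generator
  uses one convention consistently.
* **Orientation (northness)**: each stream polyline (and each connected
  ridge component of the TPI factor) gets one value
  $2 - \delta/90 \in [1,2]$, where $\delta$ is the deviation of its
  minimum-area-rectangle long axis from north. The value applies along the
  feature's rasterized footprint plus a 500-m halo (so it covers the
  decayed stream factor), nearest feature winning; elsewhere the modifier
  is neutral (1).
* **Probability indices** (cottonwood, willow, bare ground as a modifier)
  map linearly from $[0,1]$ to $[1,2]$; only the endpoints are published.
* **Thermal formation** is the bare-ground index with cultivated cropland
  cells raised to 1 (croplands are added to the thermal surface; the index
  itself stays in $[0,1]$).

Every one of these values is a named entry of `model_options()` and can be
overridden per run; overrides are logged by the pipeline so a run is
auditable against the published tables.

## Validation

The occurrence chain is: drop records with positional error worse than
400 m; thin greedily in descending quality order so no kept point is
within 800 m of a better-quality kept point (the greedy pass is
idempotent); subsample at random to at most 10 records per species,
warning below 50 total. The published accuracy wording, read literally,
would discard the *most precise* records; the implementation defaults to
the evident intent and exposes the literal reading as
`direction = "min_error"` in `filter_by_accuracy()`.

The Boyce index ranks the validation points by model score and splits them
into $k$ (default 10) nearly point-balanced bins. The nominal threshold
between bins is the midpoint of the two scores straddling the break, as
reported in `boyce()` output. Bin *membership*, however, is decided by
rank against the straddling scores themselves, with raster cells strictly
between two adjacent point scores joining the lower bin. The difference
only affects the area share of score values never attained by a
validation point, and it makes the whole statistic exactly invariant under
strictly increasing transforms of the model surface — a property the test
suite asserts. Breaks falling inside runs of tied scores are merged,
reducing the effective bin count (heavily zero-inflated models typically
come out with fewer than 10 bins). The index is the Spearman correlation
between bin rank and area-adjusted frequency (point share ÷ area share);
its p-value is a one-sided permutation test for positive association,
enumerated exactly for up to 8 effective bins ($8! = 40320$ orderings) and
estimated from 10,000 seeded Monte-Carlo permutations above that. No
published tie-handling or p-value method exists for this statistic at this
bin count; a permutation null is the defensible choice for $n \le 10$
ranks, where the $t$ approximation is poor.

Expert scoring multiplies each reviewer's model rating
($\{-1,-0.5,0,0.5,1\}$) by their self-rated expertise
($\{1,1.25,1.5,1.75,2\}$) and averages the products; values outside those
Likert sets are rejected.

## Sensitivity and exposure

`enumerate_partials()` produces one partial model per factor (term
removed), per modifier (modifier removed, i.e. set neutral) and per
non-unit weight (reset to 1) — 13 partials for the wetland model, 9
riparian, 7 raptor, 3 sparse grassland. Percent difference per cell is
$100\,|full - partial|/full$, computed only where the full model is
positive; no cap is applied above 100%, and the zero-cell exclusion is a
documented choice (the statistic is undefined there, and published partial
statistics exceeding 100% suggest no capping was used). Classification
accuracy is the share of cells assigned the same 5-quantile class by both
rasters; quantile breaks use type-1 (data-value) quantiles so the
classification is rank-exact, with duplicate breaks merged.

For exposure, wind potential and each MIS surface are recoded to
$\{0, 0.25, 0.5, 0.75, 1\}$ by 5-quantile rank (top 20% $\to$ 1; when tie
merging leaves fewer than five bins the remaining bins keep the *top*
levels, anchoring the best quantile at 1) and multiplied. The published
exposure class bounds leave small gaps (0.259–0.26, 0.559–0.56); they are
regularized to the half-open cover very_low $[0,0.1)$, low $[0.1,0.26)$,
moderate $[0.26,0.56)$, high $[0.56,0.75]$, very_high $(0.75,1]$, which
agrees with every printed boundary value and classifies every attainable
product. (One published worked example, $0.25 \times 0.25 = 0.125$, is
inconsistent with the stated multiplication rule, which gives 0.0625; the
rule is followed and the example treated as an arithmetic slip.)
Uncertainty is the per-cell population SD of exposure across the full and
partial models; overlap percentages of the top-two-quantile masks are
summarized as mean ± 1.96 sd/√n across models — a normal approximation
over a small n of models, reported as such.

## The synthetic landscape generator

`generate_landscape()` emulates the *structure* the models consume, not
any real geography: a sloped plane plus anisotropic Gaussian ridges (the
only landform guarantee, because TPI and updraft factors need ridges),
with a configurable fraction of north–south crest orientations (default
0.7); stream trunks that walk along local valleys with random-order
tributaries, orders 0–7, perenniality tied to order, the largest trunk
flagged as a large river; clustered wetlands (default 5 clusters × 200
wetlands, log-uniform 0.5–40 ha so all three size classes occur, and
cluster cores reach the 2/km² density threshold under a 5-km window — a
sparse wetland layer would zero the density factor everywhere); spatially
correlated categorical land cover containing every valued class, with
riparian classes along streams; smooth $[0,1]$ surfaces for cottonwood,
willow, bare ground and prairie dogs, each biased toward the terrain
context that makes its modifier meaningful; an 8-category prevailing-wind
grid; crop patches in low terrain; and a flyway mask splitting the extent
at a column (default 60% of the width). Occurrence dates fall in synthetic
per-species spring windows so the date filter is exercisable; positional
accuracy is log-normal around 100 m so the 400-m filter bites; quality
ranks are uniform on 1–5. `generate_wind_potential()` blends the ranked
continuous TPI surface (weight `ridge_weight`), an eastward gradient and
smooth noise, then rescales to $[0,1]$ — high along ridges and in the
east.

What the generator does *not* emulate: hydrologic realism (no flow
accumulation), land-cover transition structure, spatial or temporal
autocorrelation of occurrence records, observer bias, species-specific
habitat selection. Passing tests therefore demonstrate that the pipeline
computes its statistics correctly and recovers known sampling biases on
landscapes with the assumed structure — not that the four models are
accurate descriptions of any real region.

## Numerical choices and problem sizes

Grids are row-major matrices with an upper-left origin, projected meters,
Euclidean distances, `NA` as NoData; cells NoData in any required layer
are masked in the model output. Distance operators use an exact separable
squared distance transform (cell units, so equality comparisons between
per-value transforms are exact integer comparisons); focal means use
FFT convolution with edge renormalization. Determinism: every stochastic
function takes a seed, restores the caller's RNG state, and the pipeline
derives per-stage sub-seeds from one master seed.

Default problem sizes were chosen so the whole suite exercises every code
path at desk scale: 100 × 100 cells at 90 m for landscape-level checks
(the four models evaluate in under a second there), 50 × 50 for
brute-force oracle comparisons, 40 seeds for the parameter-recovery study,
2000 points for sampling-law goodness of fit. Published statewide results
depend on full-resolution GIS layers and curated occurrence archives and
are not reproducible at these sizes; the pipeline reports its own computed
values instead.

## Known limitations

* The deductive weights and class values are expert judgments; the
  sensitivity analysis quantifies how much each matters but cannot
  validate them.
* The Boyce index on a small synthetic extent is noisy once the 800-m
  thinning reduces the validation set to tens of points; the
  parameter-recovery tests use the unthinned samples for that reason.
* The normal-approximation CI over a handful of full/partial models is
  crude; it is reported because a distribution-free interval over n ≤ 14
  models would be vacuous.
* Fall-season variants for groups modeled in spring, species-level
  models, and the forest/shrubland group are out of scope, as is fitting
  the wind-development model itself — any $[0,1]$ wind-potential raster
  can be supplied.
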