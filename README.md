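# stopover

Deductive (expert-parameterized) raster models of where migratory birds
concentrate during migration, and of the exposure of those concentration
areas to wind energy development.

Landscape-scale maps of migration stopovers are scarce: occurrence data from
the migration season are too thin in much of the interior western U.S. to
fit inductive species-distribution models, yet wind development decisions
are being made now. The approach implemented here encodes what is known
about migration behavior directly as map algebra. For each of four
functional bird groups — wetland birds, riparian birds, raptors and sparse
grassland birds — a migratory importance score (MIS) is computed per raster
cell `c` as

```
MIS_c = norm( Σ_i  w_i · norm( f_ci · Π_j m_ij ) )
```

where `f_ci ∈ [0, 1]` are importance *factors* (streams, wetland density and
size, forage, topographic leading lines, updrafts, thermals, land cover,
prairie dogs), `m_ij ∈ [0, 2]` are multiplicative *modifiers* of each factor
(elevation, river proximity, flyway, stream/ridge orientation, cottonwood,
willow, structural diversity, bare ground), `w_i > 0` are weights, and
`norm(·)` rescales to a maximum of 1. The package also provides:

* a **synthetic landscape generator** (elevation with oriented Gaussian
  ridges, branching streams, clustered wetlands, categorical land cover,
  probability surfaces, prevailing-wind categories, a flyway mask, biased
  occurrence points, and a wind-potential surface), so the full pipeline
  runs and is testable with no external GIS data;
* **presence-only validation** with the Boyce index (point-balanced bins,
  midpoint thresholds, tie merging, permutation p-value) plus the
  occurrence filtering chain (accuracy filter, 800-m quality-aware
  thinning, species-stratified subsampling) and expert-weighted Likert
  scoring;
* **drop-one-term sensitivity analysis** (per-partial mean/SD percent
  difference, 5-quantile classification accuracy, per-cell uncertainty
  surface);
* a **wind-exposure overlay**: both surfaces quantile-recoded to
  {0, 0.25, 0.5, 0.75, 1}, multiplied, classified into five exposure
  levels, with SD-across-models uncertainty and top-two-quantile overlap
  percentages with 95% CIs.

## Worked example

```r
library(stopover)

stack <- generate_landscape(landscape_params(), seed = 42)  # 100 x 100 @ 90 m
model <- migration_model(stack, "wetland")
summary(model)
#> Migratory importance model: wetland birds (spring)
#> 5 terms; weights: Streams=1, Wetland density=3, Wetland size=1,
#>   Forage availability=1, Take-off/approach buffer=1
#> MIS over 10000 cells: mean 0.529 (sd 0.154), 0.0% zero
#> Quantile breaks (k_eff = 5): 0.4172, 0.4962, 0.5979, 0.649
```

The MIS surface is in [0, 1]; the quantile breaks are the five-class bins
used for mapping (the top class is the most important 20% of the
landscape). Validate against occurrence points sampled with preference for
high-score cells (`bias = 2` means a cell's sampling weight is MIS²), after
the standard filtering chain:

```r
occ <- simulate(model, seed = 1, n = 500, bias = 2)[[1]]
val <- stratified_subsample(thin_min_distance(filter_by_accuracy(occ)), seed = 2)
boyce(model, val, k = 10)
#> Boyce index: 0.503 (p = 0.06849), 10 bins (target 10), 69 points
```

The Boyce index is the Spearman correlation between each bin's rank and its
area-adjusted frequency (share of validation points ÷ share of landscape);
+1 means occurrences concentrate exactly where the model predicts. With
only 69 thinned points on a 9 × 9 km toy landscape the index is positive
but noisy — at this extent that is expected sampling behavior, not model
failure.

```r
sens <- sensitivity(model)
head(sens$table[order(-sens$table$mean_pct_diff), ], 3)
#>             dropped_label mean_pct_diff sd_pct_diff classification_accuracy_pct
#>           Wetland density         38.59       28.46                       28.33
#> Weight for wetland density         20.34       15.00                       74.21
#>  Take-off/approach buffer         14.81        7.28                       85.42
```

Dropping the wetland-density factor changes the average cell by ~39% and
reclassifies ~72% of cells — the model leans on its base factors, while
weak modifiers barely matter. Finally, the exposure overlay against a
wind-development-potential surface:

```r
wind <- generate_wind_potential(stack, seed = 3)
exposure_report(model, wind, partials = sens$partials)
#> Exposure surface: mean 0.251, 14.5% of cells in high/very high classes
#> Top-two-quantile overlap (percent):
#>                measure full_model mean ci_low ci_high
#>  pct_of_migration_area       36.3 36.6   35.9    37.4
#>       pct_of_wind_area       36.2 36.5   35.6    37.3
```

36% of the most important wetland-bird migration area falls inside the
highest-potential wind area on this landscape, and the tight CI across the
full and 13 partial models says that conclusion is robust to dropping any
single model term.

`run_pipeline(load_config())` sequences all of the above for all four
groups and writes every raster, table and report to an output directory.

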