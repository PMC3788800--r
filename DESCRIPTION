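Package: stopover
Title: Deductive Models of Migratory Bird Concentration and Exposure to Wind Development
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds expert-parameterized ("deductive") raster models of where
    migratory birds concentrate during migration, for four functional bird
    groups (wetland, riparian, raptor and sparse grassland birds). Each model
    is a weighted sum of normalized factor-times-modifier layers evaluated on a
    stack of 90-m raster and vector inputs. The package includes a synthetic
    landscape generator so the full pipeline runs without external GIS data,
    presence-only validation with the Boyce index (point-balanced bins with
    midpoint thresholds and a permutation p-value), expert-weighted Likert
    scoring, drop-one-term sensitivity and uncertainty analysis, and a
    quantile-based overlay measuring the exposure of migration concentration
    areas to wind energy development potential.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
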