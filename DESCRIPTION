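Package: nichecast
Title: Presence-Background Niche Models and Climate-Change Range Projection
    for (Sub)Arctic Mammal Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for projecting climate-change impacts on species
    distributions with presence-background maximum-entropy niche models.
    Provides synthetic landscape and virtual-species generators with known
    truth, occurrence thinning and train/test partitioning, an L1-regularized
    log-linear (maxent) model with hinge features and clamped projection,
    sensitivity-specificity threshold selection, binary-range algebra under
    full-dispersal and no-dispersal scenarios, centroid shift geometry,
    stacked species richness, community co-occurrence metrics, a
    climate-severity sensitivity experiment, and cross-species summary
    statistics. Ships machine-readable tables of published range projections
    for 61 (sub)arctic European mammals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
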