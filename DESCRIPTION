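Package: avishift
Title: Species Range Shifts and Spatial Conservation Prioritization from
    Presence-Only Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline from raw presence-only species occurrence
    records to future-climate range-shift metrics and weighted
    conservation-priority rankings. Implements occurrence cleaning and
    presence thinning, collinearity screening of climate variables, a
    penalized presence-background niche model with cloglog output and
    replicated cross-validation, MTSS threshold binarization into range
    maps, displacement vectors of range median centers, elevation-band
    diversity profiles, richness stacking, and weighted core-area zonation
    prioritization with protected-area gap statistics. A seeded synthetic
    world generator (autocorrelated climate surfaces, Gaussian-niche
    virtual species, effort-biased sampling) makes every stage testable
    against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
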