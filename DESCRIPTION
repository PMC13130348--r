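Package: thermoplast
Title: Thermal Reaction Norms, Range Position, and Landscape Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies thermal phenotypic plasticity of plant populations as
    absolute population-specific random-regression slopes over temperature
    treatments, and relates it to range position and local environmental
    heterogeneity. Provides a synthetic-data generator with known ground
    truth (range geometry, climate grids, land-cover and elevation rasters,
    individual-level trait data), trait preparation with germination
    cut-test rules, random-regression mixed-model fits with BLUP-based
    plasticity extraction, range-position metrics (distance to the N/S
    range edge, distance to the climatic niche hull edge), landscape
    heterogeneity metrics (Shannon diversity, mean perimeter-area ratio,
    average elevation roughness) in a square buffer, an AIC candidate-model
    grid over driver combinations, and LMG relative-importance variance
    partitioning.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    mgcv,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
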