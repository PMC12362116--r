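Package: perisense
Title: Perilesional Retinal Sensitivity Mapping in Geographic Atrophy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Structure-function analysis of mesopic microperimetry in eyes
    with geographic atrophy (GA). Builds the T-shaped testing grid, computes
    per-visit Euclidean distances from each test locus to the nearest GA
    pixel on binary lesion masks (with the minimum rule for multifocal
    lesions), draws locally weighted (LOESS) sensitivity-versus-distance
    curves, and fits a segmented nonlinear mixed-effects model in which mean
    sensitivity is quadratic in GA distance below an estimated knot and
    linear above it, with a time effect and a participant-visit random
    intercept estimated by exact marginal maximum likelihood. Includes a
    longitudinal synthetic-cohort generator (growing multifocal lesions,
    hierarchical noise, floor/ceiling censoring, optional 4-2 staircase
    observer) so the whole pipeline is testable without protected data, and
    a reproducible simulate-annotate-smooth-fit pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
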