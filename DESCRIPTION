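Package: livestockgrid
Title: Gridded Livestock Density from District Censuses by Random-Forest
    Dasymetric Downscaling
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downscales district-level livestock census counts to
    high-resolution gridded density surfaces. Pseudo-training points are
    placed at the most populous settlements of each district, covariates
    are extracted at the points or within movement-range buffers, and a
    random-forest regression transfers the district densities to the
    pixel level. Predictions are rescaled with a mass-conserving
    dasymetric adjustment so pixel totals reproduce the census exactly,
    and per-pixel Mann-Kendall and Sen's slope statistics summarise
    multi-year trends. A synthetic-landscape generator supplies zone
    rasters, settlement tables, covariate stacks and latent density
    surfaces with the statistical structure the method assumes, so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    caret,
    withr,
    optparse
Config/testthat/edition: 3
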