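Package: paratymp
Title: Paratympanic Sinus Volumetrics, Allometry and Middle-Ear Acoustics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for ontogenetic studies of the crocodylian
    paratympanic (middle-ear) sinus system. Measures volume and surface area of
    segmented CT label volumes, splits confluent air spaces at soap-bubble-like
    constrictions with a distance-transform watershed, computes the geometric
    mean of 27 linear skull measurements as a composite size variable, fits
    reduced-major-axis (standardized major axis) regressions on log-transformed
    variables with confidence intervals and slope tests against isometry nulls,
    and models the middle-ear air space as a Helmholtz resonator with
    flanged/unflanged end corrections. Includes synthetic growth-series and
    phantom label-volume generators with analytic ground truth so every stage
    is testable without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml,
    RNifti,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
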