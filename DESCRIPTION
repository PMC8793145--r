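Package: nanoshape
Title: Contour-Based Shape-Space Analysis of Nanoparticle Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative morphometrics for branched-nanoparticle ensembles
    imaged as dark particles on a bright background. Segments particles from
    micrograph-like images, traces sub-pixel contours, encodes each contour
    as Fourier coefficients of its radial (centroid-distance) signature,
    builds a principal-component "shape space" over pooled ensembles, and
    quantifies ensemble dispersity and pairwise distribution overlap along
    the line joining ensemble centers of gravity. Includes a parametric
    generator of star/flower/urchin/sphere contour ensembles with a
    micrograph renderer, and an overlap-gated inductive search loop that
    climbs a surrogate readout landscape over shape space.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
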