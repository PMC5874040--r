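Package: embryoalign
Title: Spatiotemporal Alignment of 4D C. elegans Embryo Fluorescence Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated spatiotemporal alignment of 4D light-sheet movies of
    developing C. elegans embryos, from pre-morphogenesis to the onset of
    muscle twitching. Temporal registration from nuclear-count curves
    (monotone Hermite interpolation, normalized least-squares offsets,
    cell-count plateau detection), embryo-intrinsic coordinate frames from
    principal moments of inertia of convex hulls of segmented nuclei,
    closed-form anisotropic length/width scale factors, bulk-rotation
    tracking about the long axis from fiducial nuclei by rigid point-set
    registration (coherent point drift, including a rotation-damped
    variant), mapping of test embryos onto a reference embryo, and
    quantification of alignment quality and nerve-ring geometry
    (bidirectional 1-micrometer overlap fractions, vector-decomposition
    plane fits, centroid and plane-angle dispersion). Includes a synthetic
    embryo-movie generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    RANN,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
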