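Package: wingcline
Title: Spatially Explicit Geometric Morphometrics of Insect Wings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting spatial population structure from
    landmark-based wing shape data and haploid SNP genotypes. Reads TPS
    landmark files, performs generalized Procrustes superimposition,
    canonical variate analysis and pairwise Procrustes distances, builds
    inter-landmark distance features, and runs spatial principal component
    analysis (sPCA) on a K-nearest-neighbour connection network with
    Moran's I, Monte-Carlo max(t) tests for global and local structure,
    and inverse-distance interpolation of scores. Includes a Hudson-type
    haploid F_ST estimator, cross-marker concordance statistics, and a
    synthetic generator of clinal wing-and-SNP datasets with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    withr,
    MASS,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
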