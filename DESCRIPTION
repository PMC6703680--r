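Package: shadegame
Title: Game-Theoretic Analysis of Shade-Avoidance Plasticity in Virtual Plant Canopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Arabidopsis-like rosettes competing for light in regular
    stands at a range of planting densities, with organ-level red:far-red
    (R:FR) perception driving petiole elongation and lamina growth
    down-regulation through a parameterised plastic response curve. A Monte
    Carlo multiband canopy ray tracer supplies per-organ absorbed
    photosynthetically active radiation and perceived R:FR; carbon is fixed by
    a negative-exponential light response and partitioned over beta-growth
    sinks by relative sink strength. Mutant-in-resident stand experiments
    yield performance matrices that are turned into discrete and smoothed
    pairwise invasibility plots, with detection and classification of singular
    strategies (convergence-stable ESS, branching points, repellers). A
    synthetic fitness-landscape generator with analytically known structure
    supports end-to-end validation of the game-theoretic stages.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    mgcv,
    ggplot2,
    rlang,
    yaml,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
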