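Package: fibrosim
Title: Fibrotic Substrate Modeling and Reentry Analysis for Ventricular Tissue Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ventricular tissue models with two representations of
    myocardial fibrosis derived from normalized late-gadolinium-enhancement
    (LGE) intensity maps: interstitial-cleft models, in which element
    connections are severed stochastically to create local no-flux
    boundaries, and core/border-zone models with regionally reduced
    conductivities. Simulates anisotropic monodomain electrical propagation
    with a human ventricular myocyte membrane model (ten Tusscher 2006 with
    an added late sodium current) and optional ionic remodeling of fibrotic
    tissue, delivers programmed S1-S4 extrastimulus pacing from segment
    centers, and automatically detects reentrant activation, traces it back
    to its initiation sites on the element-adjacency graph, extracts local
    LGE features around each site, and tests segment-level associations
    between fibrosis burden and reentry counts with negative binomial
    regression. Includes a synthetic geometry and LGE generator so the full
    pipeline runs at desk scale without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    MASS,
    methods,
    igraph,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
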