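Package: ebsim
Title: Agent-Based Simulation of Differentiation Patterns in Embryoid Bodies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rules-based 3D simulation of spatial patterning during loss of
    pluripotency in embryoid bodies. Builds spheroidal multicellular
    aggregates from rigid spheres, evolves a binary Oct4 state under
    probabilistic neighbour-feedback rules on the cell contact graph,
    classifies emergent spatial patterns into six categories, and
    quantifies pattern trajectories with undifferentiated and
    differentiated cluster numbers. A dynamic mass-spring variant adds
    unsynchronised symmetric cell division with state-specific doubling
    times, plus utilities to estimate growth rates and doubling times
    from aggregate size data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
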