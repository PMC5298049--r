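Package: vasowave
Title: Coupled Endothelial and Smooth Muscle Cell Calcium Waves on Arterial Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates intercellular calcium dynamics in gap-junction coupled
    populations of endothelial cells (ECs) and smooth muscle cells (SMCs)
    tiled over straight-tube and Y-bifurcation arterial surfaces. Provides the
    nine-ODE coupled EC/SMC unit model (IP3-mediated and calcium-induced
    calcium release, voltage-operated calcium entry, calcium-activated
    potassium channels), homocellular and heterocellular gap-junction coupling
    under healthy and pathological connexin regimes, biharmonic-PDE surface
    generation with physiological cell tiling, per-domain adaptive
    Runge-Kutta integration with periodic ghost-state exchange, agonist
    (ATP to IP3 production flux) maps including a reduced advection-diffusion
    ATP transport solver with a reactive Robin wall condition, and
    post-processing: single-unit bifurcation diagrams, space-time maps and
    calcium wave-front metrics.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    pracma,
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    yaml,
    optparse
Config/testthat/edition: 3
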