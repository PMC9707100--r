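Package: mopc
Title: Multi-Omics Periphery and Core Decomposition on Molecular Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Network tools for locating the omnigenic neighbourhood of a
    disease from multi-omics perturbation scores. Builds connectivity lines
    (CLines): largest-connected-component z-scores of perturbed gene sets
    over a ladder of perturbation-degree cutoffs; classifies their wave
    mode into omics-specific omnigenic patterns; fits a cross-cancer
    uniform curve and aligns non-conforming lines onto it by wavelet
    smoothing and dynamic time warping; extracts core (high-cutoff
    connected module) and peripheral (top-gene neighbourhood minus core)
    regions; and quantifies region relationships by network separation,
    overlap significance, excess overlap, eQTL regulation z-scores and
    distance-based disease similarity. Includes seed-deterministic
    synthetic generators with planted cores so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    fgsea,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
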