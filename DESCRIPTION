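Package: bactrack
Title: Single-Cell Bacterial Motility Analysis and Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for single-cell bacterial swimming motility in
    bulk fluids, viscous media, and semisolid agar: Crocker-Grier style frame
    linking of centroid detections into trajectories, trajectory quality
    filters, run/trap segmentation by speed threshold with spatial trap
    merging, population speed statistics, mean-square-displacement and
    diffusivity estimation, swimming-mode tabulation, and colony-spreading
    front fits. Includes an agent-based generator of swimmer trajectories
    with three run modes (push, pull, wrapped), viscosity-scaled speeds,
    agar trapping, division outcomes, and spreading series, parameterised
    for wild-type and flagellar-stator mutant phenotypes of Pseudomonas
    putida.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
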