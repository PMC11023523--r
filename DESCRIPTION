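Package: defectflow
Title: Active Elastic Solid Simulation and Velocity-Field Topology Analysis
    for Collective Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how epithelial monolayers self-organize into
    long-range polar order. Simulates a monolayer as an active elastic solid:
    self-propelled particles on a disordered bead-spring network built by
    disk packing and Voronoi tessellation, with polarity that turns toward
    the local velocity. Analyses PIV-like gridded velocity fields for +1/-1
    topological defects via an eight-neighbor winding-number algorithm,
    links defects into tracks, calls vortex-antivortex annihilation and
    proliferation events, and computes order metrics (mean speed, spatial
    velocity correlation length, vorticity) together with trajectory-level
    kinematics (anchor-registered relative motility, pairwise
    squared-distance diffusion). Includes synthetic velocity-field and
    trajectory generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deldir,
    dplyr,
    FNN,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
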