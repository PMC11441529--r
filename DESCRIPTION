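Package: sktraj
Title: Trajectory Analysis of Lipid-Dependent Gating in Small-Conductance
    Potassium Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics trajectories of
    tetrameric SK (small-conductance calcium-activated potassium) channels
    in lipid membranes, centred on the role of the signalling lipid PIP2.
    Tracks lipid-protein salt bridges with a centre-of-charge protocol,
    builds per-lipid binding-site itineraries with transient/transfer/
    activation site classification, profiles the channel pore (HOLE-style
    spherical-probe radii), measures intracellular-gate distances with
    geometric averaging, assigns potassium ions to selectivity-filter
    sites and counts complete permeation events to estimate single-channel
    conductance, computes Shrake-Rupley solvent-accessible surface areas
    stratified by lipid-bound state, and clusters conformational poses
    conditioned on a named salt bridge. Includes a synthetic-trajectory
    generator with programmable ground truth so every analysis stage is
    testable without simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    cluster,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
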