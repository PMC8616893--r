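Package: avmflow
Title: Virtual Embolization and Blood-Flow Visualization Pipelines for
    Cerebral Arteriovenous Malformations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scriptable toolkit for desk-scale virtual embolization studies of
    cerebral arteriovenous malformations (AVMs). Generates seeded synthetic AVM
    vascular networks (parent artery, feeders, nidus, draining veins, veins),
    enumerates all 2^N blocked/unblocked feeder variants, solves steady laminar
    incompressible flow on the vessel graph with a Hagen-Poiseuille/Kirchhoff
    reduced-order model under fixed-inflow and zero-pressure-outlet boundary
    conditions, reconstructs Cartesian 3D velocity fields with laminar
    parabolic profiles, reads and writes the binary VF 3D-texture vector-field
    format and legacy ASCII VTK, and advects seeded particle populations with
    Euler or RK4 integration, velocity color scales and view-angle ghosting
    weights. An end-to-end pipeline produces per-variant flow reports, VF
    files, particle snapshots and a checksummed run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    withr,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
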