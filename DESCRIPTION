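Package: mechanocell
Title: Mechanochemical Simulation of Single-Cell Migration and Spreading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Agent-based mechanochemical simulator of a single adherent cell on
    ligand-coated planar substrates and micropatterned geometries. The cell is a
    pair of closed triangulated elastic membranes (cortex and nucleus) coupled to
    the substrate through stochastic integrin-ligand focal adhesions (Bell slip
    bonds), contracted by sarcomeric stress fibers with a Hill force-velocity
    law, and pushed by a constant lamellipodium force at the leading edge.
    Overdamped quasi-static dynamics are integrated with an adaptive linearly
    implicit scheme. Includes micropattern ligand-field generators (disk, pacman,
    crossbow), migration-speed, traction-stress and stress-fiber-lifetime
    analyses, and VTK/PLY mesh export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
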