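Package: pfmsim
Title: Explicit Finite-Element Simulation of Fetal-Head Descent Through the
    Pelvic Floor Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale biomechanical model of the second stage of labor: a
    rigid spherical fetal head descends under gravity through a deformable
    pelvic-floor-muscle (PFM) sheet.  Provides a parametric hammock-with-hiatus
    geometry generator with structured tetrahedral meshing, a total-Lagrangian
    Saint Venant-Kirchhoff element kernel, node-to-analytic-sphere penalty
    contact with regularized Coulomb friction, central-difference explicit time
    integration with an energy ledger, and postprocessing of equivalent (von
    Mises) stress, principal stress/strain, displacement extrema and extension
    ratios for biparietal diameters of 80, 90 and 100 mm.  Field output is
    written as VTK series; metrics as CSV/JSON; meshes can be exported to
    Abaqus INP and Gmsh MSH.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
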