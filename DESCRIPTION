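Package: cellscale
Title: Multi-Scale Finite Element Coupling of Joint Loading to Chondrocyte Deformation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processes a macro-scale hexahedral finite element solution of a
    loaded joint into cell-level deformation metrics. Deformation gradients are
    extracted at element centroids (or Gauss points) from undeformed and deformed
    nodal positions, filtered for deforming elements, and used to drive affine
    displacement boundary conditions on independent micro-scale models of
    chondrocytes embedded, with their pericellular matrix, in an extracellular
    matrix block. Micro models are solved with a total-Lagrangian hexahedral
    solver for uncoupled Mooney-Rivlin hyperelasticity using a mean-dilatation
    formulation, and cell deformation is summarized by inertia-ellipsoid aspect
    ratio changes, volumetric strain, volume-averaged effective (von Mises)
    strain and stress, and maximum shear strain. Batches of micro models run in
    parallel with per-job failure containment, and results feed through-origin
    regressions, quartile summaries, and material sensitivity studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
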