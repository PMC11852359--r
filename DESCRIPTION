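Package: cytofem
Title: Finite-Element Mechanics of Tensegrity Cells Embedded in an
    Extracellular Matrix
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear finite-element simulation of single cells and
    small cell groups embedded in an elastic extracellular-matrix (ECM)
    block under external pressure. Each cell is modelled as a nucleus and
    cytoplasm (linear tetrahedra), a cortex and nuclear membrane
    (constant-strain triangular membranes), and a prestressed six-strut
    tensegrity cytoskeleton (bars for microtubules, pre-tensioned tendons
    for actin). A structured multi-block mesher produces conforming
    multi-region meshes; a total-Lagrangian Newton-Raphson solver applies
    cytoskeletal prestress and surface pressure in increments; stress
    recovery reports Huber-Mises-Hencky (von Mises) equivalent stress per
    component and uniaxial stress in cytoskeleton members. Includes a
    scenario pipeline comparing stiff and soft ECM variants for single
    cells and an 18-cell group, with CSV summary tables and VTU field
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
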