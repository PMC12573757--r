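Package: qedhf
Title: Cavity QED Hartree-Fock with Analytical Nuclear Gradients and
    Field-Aware Geometry Optimization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Self-consistent-field electronic structure for molecules coupled
    to quantized cavity modes and static electric or magnetic fields.
    Implements closed-shell cavity quantum-electrodynamics Hartree-Fock
    (QED-HF) in the coherent-state basis over uncontracted Gaussian basis
    sets, the analytical nuclear gradient of the QED-HF energy including
    static-electric-field terms, finite-difference gradients for magnetic
    fields at a fixed gauge origin, and the machinery built on top of them:
    geometry optimization retaining rotational degrees of freedom,
    rigid-rotation potential-energy scans, constrained-dihedral scans, and
    coupling-strength sweeps of optimized internal coordinates.  A compiled
    McMurchie-Davidson integral engine supplies all one- and two-electron
    integrals and their nuclear-coordinate derivatives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
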