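Package: chargebem
Title: Charge-Based Boundary Element Forward Modelling for EEG/MEG with
    Adaptive b-Refinement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Matrix-free charge-based boundary element method (BEM) for the
    EEG/MEG forward problem on nested piecewise-homogeneous head models. The
    unknown is the induced surface charge density on conductivity interfaces;
    the integral operator is applied matrix-free with analytic near-field
    triangle integrals and solved by GMRES. A one-time adaptive mesh
    pre-refinement ("b-refinement") driven by the right-hand-side charge
    estimate resolves the near-singular dipole source region before the
    solve. Includes four-layer concentric-sphere fixtures, closed-form
    multilayer-sphere EEG and Sarvas MEG reference solutions, RDM/L2 error
    metrics, and a small lead-field / minimum-norm source localization layer.
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
    jsonlite,
    withr
Config/testthat/edition: 3
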