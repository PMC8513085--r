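Package: espfqmm
Title: Electrostatic-Potential-Fitted QM/MM with Excited-State Gradients and
    Conical-Intersection Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Electrostatic embedding QM/MM based on electrostatic-potential
    fitting (ESPF) charge operators. Provides a self-contained Gaussian-basis
    restricted Hartree-Fock and configuration-interaction-singles (Tamm-Dancoff)
    electronic-structure backend, the ESPF fitting grid and charge-conservation
    corrected embedding Hamiltonian, analytic ground- and excited-state QM/MM
    nuclear gradients with finite-difference validation, a classical solvent
    engine with droplet packing, and minimum and conical-intersection
    optimizers using the branching-plane update method, for mapping the
    photochemical critical points of a chromophore in a solvent droplet.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
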