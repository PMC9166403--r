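Package: frpefit
Title: Fibril-Reinforced Poroelastic Cartilage Model, Indentation Simulation
    and Inverse Parameter Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the fibril-reinforced poroelastic (FRPE) constitutive
    model of articular cartilage (tension-only collagen fibril network over a
    neo-Hookean non-fibrillar matrix saturated by Darcy fluid flow with
    strain-dependent permeability), an axisymmetric large-deformation
    displacement/pore-pressure mixed finite-element engine with rigid
    spherical-indenter contact, stress-relaxation / unconfined / confined
    compression protocols, and inverse identification of the material
    parameters from force-relaxation curves by multi-start Nelder-Mead
    minimisation of a normalised mean squared error. Includes a synthetic-data
    generator with known ground truth for end-to-end recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
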