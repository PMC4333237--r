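Package: pulmopk
Title: Pharmacometric Modeling of Pulmonary Drug Distribution from
    Bronchoalveolar Lavage Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and nonlinear mixed-effects estimation of a
    pharmacometric pulmonary model describing drug distribution from plasma
    to epithelial lining fluid (ELF) and alveolar cells (AC) sampled by
    bronchoalveolar lavage, using rifampicin as the reference compound.
    The plasma submodel combines transit-compartment absorption, a
    one-compartment disposition model, enzyme turn-over autoinduction of
    oral clearance and allometric scaling with body weight, fat-free mass
    or normal fat mass.  ELF and AC penetration is described by effect
    compartments parameterized by an equilibration rate constant and a
    pseudo-steady-state concentration ratio.  Includes a synthetic-study
    generator emulating sparse BAL designs, a Laplace-type (FOCE with
    interaction) marginal-likelihood estimator with likelihood-ratio
    testing and standard errors, and prediction-corrected visual
    predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    ggplot2,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
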