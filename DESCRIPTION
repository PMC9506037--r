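Package: cpaeos
Title: Cubic-Plus-Association Equation of State for CO2 Mixtures with
    Glycols, Glycerol and Biodiesel Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the cubic-plus-association (CPA) equation of state,
    combining the Soave-Redlich-Kwong cubic term with a Wertheim-type
    association term, for phase-equilibrium modeling of mixtures of
    supercritical carbon dioxide with polyethylene glycols, glycerol,
    triglycerides, fatty acids and fatty-acid methyl esters. Provides a
    bundled pure-fluid and binary parameter registry, molecular-weight
    correlations for polyethylene-glycol parameters, vapor-liquid
    equilibrium solvers (pure saturation, bubble and dew points,
    isothermal flash, isotherm tracing), binary-interaction-parameter
    regression with phase-specific objectives, and a synthetic
    pseudo-experimental data generator for testing the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
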