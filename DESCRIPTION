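Package: warburgsim
Title: Dynamic Modelling of Tumor Central Carbon Metabolism and Metabolic Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Kinetic modelling of tumor xenograft growth driven by a
    two-compartment central-carbon-metabolism network (capillary blood
    microenvironment perfusing a tumor-cell compartment).  Provides the
    stoichiometric network reconstruction for LL/2 Lewis lung carcinoma,
    Michaelis-Menten kinetics with multiplicative drug-effect factors
    (diclofenac, alpha-lipoic acid, hydroxycitrate, metformin), stiff ODE
    simulation of tumor volume with a redox-gated death term, elementary
    flux mode and minimal cut set enumeration, weighted least-squares
    parameter estimation, and a synthetic mouse-cohort generator for
    testing estimation pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
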