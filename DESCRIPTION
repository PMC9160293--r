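Package: aedesgm
Title: Spatial Population Dynamics of Aedes aegypti Under Genetically
    Modified Male Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reaction-diffusion model of Aedes aegypti population dynamics
    (egg, aquatic, female, wild-male and genetically modified male phases) on
    heterogeneous house-block/street rasters, with a finite-volume
    Crank-Nicolson solver, the single-cell total-population reduction, wild
    and GM-perturbed equilibrium analysis (basic offspring number, Cardano
    cubic roots, critical release rates), carrying-capacity calibration, and
    release-strategy experiments (localization, heterogeneity, release
    frequency scans).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    deSolve,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
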