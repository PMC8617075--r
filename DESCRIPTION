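Package: plumeMTS
Title: Thermodynamic Modelling of Microbial Biomass Production in
    Hydrothermal Plumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Couples a one-dimensional Morton-Turner buoyant plume model
    with a guild-structured microbial community model based on Microbial
    Transition State (MTS) theory of growth to predict chemolithoautotrophic
    and chemoorganotrophic biomass production rates in non-buoyant
    hydrothermal plumes, and extrapolates the predicted rates to areal and
    global deep-ocean organic carbon budgets. Includes Gibbs-energy
    machinery (formation energies, activity corrections, Heijnen
    dissipation energies, Kleerebezem lambda coupling), a stiff 18-guild
    community ODE system, a heat-flux saturation model for heterotrophic
    production, and a synthetic vent-site generator for download-free
    testing of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
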