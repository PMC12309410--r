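Package: seepflux
Title: Hydrothermal Seep Sediment Geochemistry and Nutrient-Flux Budgets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies hydrothermal mobilization of ammonium and nutrient
    metals from organic-rich seep sediments. Provides Al-normalized element
    enrichment factors, shale-normalized rare-earth indices and Eu anomalies,
    steady-state advection-diffusion inversion of thermal-probe profiles for
    Peclet number and Darcy seepage velocity, piecewise exponential modelling
    of sedimentary nitrogen loss with remobilization timescales and areal
    fluxes, Rayleigh nitrogen-isotope mass balance, and basin-scale flux and
    productivity upscaling under Redfield stoichiometry. Includes seeded
    synthetic core-profile generators so the full pipeline can be exercised
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
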