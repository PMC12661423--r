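Package: seeddry
Title: Mechanistic Single-Seed Drying Simulation with Non-Equilibrium
    Sorption Isotherms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates coupled heat and mass transfer in a single shrinking
    spherical seed during convective drying, using a Lagrangian equal-volume
    shell finite-volume discretisation closed by Flory-Huggins sorption
    isotherms with glassy-state corrections (free-volume and Leibler-Sekimoto
    elastic additions), a moisture- and temperature-dependent Arrhenius
    diffusivity, and Ranz-Marshall boundary-layer transfer coefficients.
    Includes least-squares fitting of isotherm and diffusivity parameters from
    sorption and diffusivity tables, a percent-error statistic for comparing
    simulated and experimental drying curves, image-based mixing-entropy
    analysis of fluidised seed beds, and deterministic synthetic-data
    generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
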