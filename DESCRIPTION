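Package: hemodrop
Title: Evaporation Dynamics and Deposit Topography of Sessile Blood Droplets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sessile blood-droplet evaporation
    experiments on heated substrates. Provides thermophysical property
    models for whole blood (viscosity, thermal diffusivity, surface
    tension fits), reduction of infrared thermography frame stacks to
    edge-centre temperature differences, thermal Marangoni number
    trajectories with two-segment rate analysis and regime
    classification, droplet-geometry descriptors (contact angles,
    volume-shrinkage slopes, volume-diameter scaling), an ISO
    25178-style areal surface-texture engine for dried-deposit height
    maps (height, functional, volume, feature and pattern parameters),
    and the study-level statistical layer (one-way ANOVA, Tukey-Kramer
    multiple comparisons, temperature and temperature-volume
    regressions). A synthetic-data generator emulates a full
    four-temperature, 18-replicate study so every stage is testable
    without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
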