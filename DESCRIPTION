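Package: swarmphage
Title: Motion Statistics, Transport Modelling and Image Quantification
    for Swarm-Mediated Phage Delivery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for experiments in which bacterial swarms
    actively transport bacteriophages toward prey colonies and biofilms.
    Reads single-particle tracking exports (tracker XML or CSV) and
    calibrated fluorescence image stacks, computes ensemble mean-squared
    displacement, anomalous-diffusion exponents and Einstein-relation
    diffusivities, predicts transport distances with one-dimensional
    Fickian and advection-diffusion finite-difference solvers, and
    quantifies prey-biomass clearance and phage depth penetration from
    timelapse and confocal z-stack images. A synthetic-data module
    generates Brownian, fractional-Brownian and advective trajectories
    plus colony-timelapse and biofilm z-stack scenes with known ground
    truth, so every analysis stage is testable without raw microscopy.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xml2,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
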