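Package: zbdry
Title: Coupled Heat-Moisture Drying Simulation, Kinetics and Quality Scoring for Sichuan Pepper
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the convective (HAD), pulsed-vacuum infrared (PVD)
    and microwave-vacuum (MVD) drying of Zanthoxylum bungeanum pericarp. Provides a
    one-dimensional finite-volume solver for the coupled energy and moisture
    transport equations with mode-specific volumetric heat sources, a
    pressure-deficit evaporation sink and convective boundary conditions;
    thin-layer Page drying-kinetics fitting and Arrhenius activation-energy
    estimation; CIELAB colour-difference, Chauvenet outlier rejection,
    dehiscence-rate and amide-content computations feeding a min-max
    normalisation, entropy-weighting and comprehensive-score chain;
    goodness-of-fit and Pearson-correlation validation utilities; and
    deterministic synthetic-data generators that emulate the experimental design
    so every stage of the pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
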