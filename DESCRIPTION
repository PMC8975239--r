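Package: cpsim
Title: Lumped-Parameter Cardiopulmonary Simulation of Heart-Lung
    Interactions During Mechanical Ventilation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fixed-step simulation of a closed-loop lumped-parameter
    cardiopulmonary model for studying heart-lung interactions under
    positive-pressure ventilation. The heart is a four-chamber
    variable-elastance model with an interventricular septum solved
    algebraically at every step and an exponential pericardial membrane;
    the pulmonary circulation separates extra-alveolar arterioles from
    alveolar-referenced capillaries with a shunt branch and an
    arteriolar resistance that grows quadratically with lung volume;
    short-term arterial baroreflex control modulates heart period, wall
    elastances, peripheral resistances and venous unstressed volume.
    Includes a simple ventilator model (PEEP, pressure support,
    rate/I:E, end-inspiratory pause), beat and breath analysis (stroke
    volume variation, pulse-pressure variation, preload/afterload
    indices) and ready-made ventilation protocols (PEEP steps, volume
    expansion, elastance-partitioning and sensitivity sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
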