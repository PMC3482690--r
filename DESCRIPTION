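Package: plumebot
Title: Closed-Loop Simulation and Evolution of Neural Olfactorimotor Control
    in Virtual Odor Plumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated platform for studying odor source localization by a
    simulated robot under neural control. Provides an interactive
    two-dimensional stable-fluids solver carrying multiple odorant dye channels,
    with wind sources, evaporation, internal boundaries and perturbation of the
    flow by the moving robot; a motif-based olfactory sensor model with
    first-order binding kinetics; a five-stage layered sensorimotor circuit
    (sensors, mitral relay, feedforward inhibition, branch-thresholded cortical
    pyramids, motor units) with per-class synaptic depression and homeostatic
    excitability; a size-principle mapping from motor units to signed tread
    currents; a five-state exploratory behavior controller; and a genetic
    algorithm that evolves the circuit parameters against time-to-source
    fitness over repeated closed-loop trials. Results are returned as tibbles
    with tidy(), glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    callr,
    withr,
    tidyr
Config/testthat/edition: 3
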