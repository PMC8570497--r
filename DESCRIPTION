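Package: prespike
Title: Ephaptic Coupling Through the Synaptic Cleft of Giant Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ephaptic coupling through the synaptic cleft of
    giant synapses such as the calyx of Held. Implements a lumped-circuit model
    of the cleft with closed-form predictions for the capacitive and resistive
    dissipation regimes, an ODE simulator with Markov-state voltage-gated
    channels whose gating feeds back on the cleft potential, analytic
    cleft-geometry relations (potential profiles, prespike scaling, cleft
    conductance and extracellular resistivity), and an estimation pipeline that
    recovers the cleft time constant, conductance and capacitance from paired
    voltage-clamp recordings. A synthetic-recording generator with known ground
    truth emulates action-potential-waveform trains, presynaptic calcium
    currents and the P/5 leak-subtraction protocol so the whole pipeline can be
    exercised and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
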