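Package: morphoswitch
Title: Toggle-Switch Models of BMP-FGF Cross-Inhibition and Border Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of cross-inhibition between
    the BMP and FGF morphogen signalling pathways in the developing dorsal
    forebrain. Enumerates and classifies the 81 two-link cross-inhibition
    topologies into simple target inhibition, simple upstream inhibition,
    coherent feedforward and cross-inhibitory positive feedback (toggle
    switch) classes; computes steady states by closed form, numerical
    integration and monotone open-loop analysis; characterises dose-response
    curves by maximum level, EC50 and apparent Hill coefficient; measures
    hysteresis and bistability windows; simulates washout protocols with
    persistent ligand signalling; analyses dual toggle loops with distinct
    EC50 values; and models one-dimensional tissue border formation and
    scaling under opposing exponential morphogen gradients. Includes
    synthetic-data generators emulating noisy RT-qPCR dose responses and
    spatial gradient profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
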