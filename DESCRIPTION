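Package: prfield
Title: Two-Compartment CA3 Pyramidal Neuron Model with Extracellular
    Resistance Under Weak Alternating Electric Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Pinsky-Rinzel-type two-compartment hippocampal CA3
    pyramidal neuron electrically coupled to an explicit extracellular
    resistance network and driven by a weak sinusoidal electric field.
    Provides the ionic-current machinery (Hodgkin-Huxley gating kinetics,
    calcium dynamics, NMDA/AMPA synaptic gates), the quasi-static Kirchhoff
    solution of the extracellular equivalent circuit, a stiff ODE simulation
    front end, spike detection with firing-rate and phase-locking-ratio
    statistics, and a parameter-sweep engine for characterizing neuronal
    field sensitivity as a function of extracellular resistance and
    potassium reversal potential.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
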