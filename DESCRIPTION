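Package: voltclamp
Title: Simulation and Analysis of Whole-Cell Voltage-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for whole-cell voltage-clamp electrophysiology of
    voltage-gated ion channels: current-voltage (I-V) and steady-state
    inactivation Boltzmann fitting, activation kinetics, r250 and slow
    inactivation metrics, ON-gating-charge integration, and non-stationary
    fluctuation analysis (NSFA) of tail currents.  Includes a stochastic
    binomial channel-ensemble simulator that produces synthetic sweep sets
    with recorded ground truth, so that every analysis stage can be
    validated by parameter recovery.  A plain-text sweep exchange format
    with bit-exact round trips is provided for interoperability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
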