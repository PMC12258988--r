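Package: mnbistab
Title: Conductance-Based Modelling of Spinal Motoneuron Bistability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley-type model of a spinal
    motoneuron with eight ionic currents and intracellular calcium dynamics
    including calcium-induced calcium release (CICR). Provides adaptive
    Dormand-Prince 5(4) integration of arbitrary injected-current programs
    (ramps, steps, pulses, holding ladders), ramp-hysteresis detection of
    bistability thresholds (I_up, I_down), equilibrium finding and stability
    classification, one- and two-parameter bistability maps, and
    electrophysiological trace quantification (slow afterdepolarization
    metrics, firing-rate profiles, three-criterion bistability assessment).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
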