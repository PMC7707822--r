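Package: locoresp
Title: Locomotor-Respiratory Coupling Analysis for Running Rodents
Version: 0.1.0
Authors@R: person("locoresp", "maintainers", email = "locoresp@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether inspiratory events are phase-locked to the
    stride cycle in running rodents. Detects inspiratory bursts in diaphragm
    EMG and derives per-cycle respiratory parameters (Ti, Te, instantaneous
    frequency, normalized amplitude); segments limb pose tracks into
    footfall-delimited stride cycles with stance/swing phases and classifies
    trot versus gallop; assigns each inspiration a phase within the stride
    cycle and evaluates phase concentration with circular statistics and a
    fixed mean-resultant-length criterion; computes surrogate-calibrated
    cross-correlograms and Mann-Whitney condition comparisons. A synthetic
    generator produces coupled or uncoupled locomotor-respiratory sessions
    with known ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
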