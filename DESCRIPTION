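Package: abasim
Title: Kinetic Simulation and Calibration of Abscisic Acid Signaling and a
    Bioluminescent Whole-Cell Biosensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Ordinary-differential-equation models of abscisic acid (ABA)
    hormone signaling (SnRK2/PP2C/MAPK, with and without ABA) and of an
    ABA-responsive bioluminescent whole-cell biosensor (Hill-type receptor
    binding, reporter transcription and translation, cumulative
    luminescence). Provides adaptive and fixed-step reference integration,
    steady-state detection, dose-response sweeps over initial ABA, local
    sensitivity analysis, Hill-curve and full-model nonlinear least-squares
    calibration, a seeded synthetic-plate generator, YAML run configuration,
    CSV/JSON outputs with provenance sidecars, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
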