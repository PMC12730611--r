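Package: moodswing
Title: Backstepping Treatment Control of a Bipolar II Mood Oscillator
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models Bipolar II mood dynamics as a Lienard (van der Pol type)
    oscillator whose untreated limit cycle represents the hypomanic/depressive
    mood swing, and implements two backstepping treatment controllers that
    quench the swing by driving mood and its change rate to the zero
    equilibrium: an exact-model-knowledge law that cancels the plant drift
    using the true patient parameters, and an adaptive law that replaces them
    with a gradient-updated estimate. Provides deterministic closed-loop
    simulation (fixed-step RK4 or an adaptive stepper), Lyapunov-based
    diagnostics (exponential decay envelopes, quenching and estimate
    convergence reports), bundled reference scenarios, YAML scenario
    configuration, exact round-trip CSV trajectory output, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    utils,
    yaml
Suggests:
    jsonlite,
    Matrix,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
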