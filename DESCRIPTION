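Package: perspectr
Title: Two-Timescale Double-Well Dynamics of Perspective-Taking Decisions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates perspective-taking decisions as two coupled stochastic
    accumulation processes descending a tilted double-well potential at
    different timescales. A fast "potentiation" process and a slow
    "simulation" process each follow noisy gradient descent on the quartic
    potential V(x) = k*x - x^2/2 + x^4/4, optionally pulled toward one
    another by coupling terms; a decision is declared when the running sum
    of either coordinate first reaches a threshold in absolute value.
    Provides the pure dynamical maps, seeded single-trial and batch
    simulation with accumulator-threshold stopping, noise-free landscape
    analysis (vector fields, fixed points, stability via the map Jacobian),
    canonical parameter presets for four qualitative regimes, parameter
    sweeps, YAML configuration, tidy tabular export, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
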