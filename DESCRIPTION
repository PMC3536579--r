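Package: fimdesign
Title: Fisher-Information-Driven Experiment Selection for Gene Network
    Parameter Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, penalized nonlinear least-squares fitting, and
    greedy optimal experiment selection for a six-gene regulatory network
    modelled by ordinary differential equations. Implements the
    A-optimality-style selection criterion based on the Fisher information
    in log parameters, a prediction-targeted variant, a synthetic data
    generator with additive and multiplicative Gaussian noise, and
    cost-landscape diagnostics (distinct-minimum classification, cost
    barrier profiles, principal-angle comparison of sloppy subspaces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
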