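Package: durobust
Title: Dynamics and Duration Robustness of Linear Signaling Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the relaxation of linear phosphorylation cascades
    (the Heinrich model, its linearization about the deactivated state, and
    the Huang-Ferrell mass-action MAPK model) after removal of a sustained
    stimulus, and quantifies how robust the temporal profile and the
    response half-life are to perturbations of kinase and phosphatase
    activities. Provides closed-form steady-state phosphorylation levels,
    exponential-chain solutions of the linearized cascade, logarithmic-gain
    sensitivity analysis, an L2 similarity measure between consecutive
    relaxation profiles, duration-robustness condition checks, parameter
    sweep pipelines, and a generator of kinetically organized synthetic
    parameter sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
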