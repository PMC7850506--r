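Package: ecoevocycle
Title: Eco-Evolutionary Dynamics of Aggregative Multicellularity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and analyses a three-variable eco-evolutionary model of
    a cell population with fast- and slow-moving motility types competing for
    a shared logistic resource. Fast cells feed efficiently alone; slow cells
    exploit collective transport inside aggregates, a public-goods conflict.
    The package locates and classifies equilibria, detects the supercritical
    Hopf bifurcation that gives rise to emergent "life-like" limit cycles of
    aggregation and dispersal, extracts cycle observables (period, amplitudes,
    group partition, generation-time ratios), and runs adaptive-dynamics
    analyses of the exploitation trait: analytic, cycle-averaged and direct
    simulation estimates of invasion fitness, and trait substitution
    sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
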