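Package: scyphodyn
Title: Polyp-Medusa Life-History Dynamics of Scyphozoan Jellyfish
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for a two-stage (benthic polyp,
    pelagic medusa) ordinary-differential-equation model of scyphozoan
    jellyfish population dynamics. Provides the six-parameter reduced
    system, trajectory simulation with an adaptive integrator, computation
    and local-stability classification of all equilibria, the global-regime
    trichotomy (extinction, polyp-only survival, coexistence),
    temperature-dependent budding and strobilation response curves with
    least-squares fitting, per-degree growth stairs, and steady-state
    sensitivity sweeps over temperature, substrate competition, and
    predation pressure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
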