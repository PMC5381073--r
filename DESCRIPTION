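Package: presspulse
Title: Transient Predator-Prey Dynamics in Serially Diluted Microcosms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discrete-time Lotka-Volterra simulation of a serially diluted
    bacterium-ciliate microcosm under press and pulse disturbance regimes.
    Provides the daily-dilution predator-prey map with predator coupling to
    an alternative resource, two-stage parameter calibration (Nelder-Mead
    fits to single-species and co-culture growth curves followed by Latin
    hypercube refinement under a fourth-power relative-distance objective),
    transient-dynamics metrics (Nash-Sutcliffe efficiency, equilibrium
    bands, response and recovery times, deviation time, windowed
    prey-predator covariance for diagnosing prey release), simulation
    sweeps over press duration, pulse strength and resource coupling, and a
    synthetic-data generator emulating replicated daily counts and hourly
    growth curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'model-core.R'
    'disturbance.R'
    'metrics.R'
    'calibration.R'
    'experiments.R'
    'synthetic-data.R'
    'io.R'
    'config.R'
    'cli.R'
    'show-methods.R'
    'presspulse-package.R'
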