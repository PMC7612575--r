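Package: axontrace
Title: Graph-Based Axonal Branch Reconstruction and Conduction Velocity
    Estimation from High-Density Microelectrode Array Templates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automated reconstruction of axonal branches and estimation
    of action-potential conduction velocities from extracellular templates
    ("electrical footprints") recorded on high-density microelectrode arrays.
    Channels carrying axonal signal are selected with amplitude, kurtosis,
    peak-time-dispersion and initial-delay filters; a directed propagation
    graph is built over the selected electrodes and optimal paths towards the
    initial (largest-amplitude) channel are extracted with a shortest-path
    search driven by amplitude and distance heuristics; each branch's
    conduction velocity is then estimated by a robust Theil-Sen fit of
    cumulative path distance against peak latency, with MAD-based outlier
    removal and jump splitting. The package also ships a phenomenological
    synthetic footprint generator with known planar arbors and a ground-truth
    evaluation module (branch matching, tracking and velocity errors).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
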