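Package: hormcoh
Title: Diurnal Hormone Rhythms and Wavelet-Coherence Functional Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for dense-sampling brain-hormone studies: simulation of a
    40-session diurnal design with known hormone-coupled connectivity,
    nuisance processing of regional BOLD timeseries (framewise displacement,
    Friston-24 expansion, spike regressors, global scaling, detrending,
    residualization), wavelet band-limited magnitude-squared coherence
    connectomes, edgewise standardized regression of coherence against
    hormone timeseries with a permutation null and false-discovery-rate
    control, signed nodal association strengths summarized over nine
    canonical networks with two-way ANOVAs and Tukey HSD, and weighted graph
    metrics (within-network global efficiency, participation coefficient)
    compared between morning and evening sessions.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
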