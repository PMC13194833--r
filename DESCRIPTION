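Package: eegnetrel
Title: Reliability-Screened Resting-State EEG Connectivity and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for directed functional brain
    connectivity from multichannel resting-state EEG. Generates synthetic
    cohorts with known multivariate autoregressive (MVAR) coupling, zero-lag
    volume-conduction mixing and scripted artifacts; preprocesses recordings
    (epoching, notch/band-stop/FIR filter chain, artifact subspace
    reconstruction, ICA-based component rejection); estimates connectivity by
    the directed transfer function (DTF), imaginary coherence (iCOH) and
    weighted phase lag index (wPLI); binarizes networks by
    minimum-spanning-tree seeded fixed-density thresholding; computes six
    directed graph indices (modularity, global and local efficiency,
    clustering, transitivity, assortativity); screens them by ICC(3,k)
    test-retest reliability across epochs; and tests group differences with
    random-intercept linear mixed-effects models, Benjamini-Hochberg FDR
    correction and Cohen's f2 effect sizes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    lmerTest,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
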