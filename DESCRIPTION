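Package: meaculture
Title: Synchrony, Spectral and Complexity Analysis of Cortical Cultures on Micro-Electrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spontaneous and stimulus-evoked dynamics of
    dissociated cortical networks recorded on 60-channel planar micro-electrode
    arrays (MEAs). Implements local-field-potential band power via Welch spectra,
    multi-unit burst and synchrony metrics (mean firing rate, inverse burst ratio,
    burstiness index, spike time tiling coefficient, SPIKE synchronization),
    post-stimulus time histogram response statistics with stability-threshold
    channel classification, neural complexity from bias-corrected mutual
    information over random network bipartitions, and a spiking (or LFP-based)
    perturbational complexity index built from bootstrap-significant evoked
    activations compressed with Lempel-Ziv. A synthetic-culture generator emulates
    the synchronized slow-oscillation (basal) and cholinergically desynchronized
    regimes so that every stage of the pipeline can be exercised and tested
    without experimental recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    pracma,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
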