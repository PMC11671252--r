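Package: ecogflow
Title: Category Decoding and Directed Spectral Connectivity for
    Multichannel Field Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis chain for discovering stimulus-category information
    and directed functional connectivity in trial-epoched multichannel
    electrocorticographic (ECoG) field potentials. Provides a synthetic
    session generator with known band-limited category effects and an
    embedded multivariate autoregressive subnetwork, signal conditioning
    (zero-phase filtering, common-average re-referencing, vertical bipolar
    derivation), multitaper event-related spectral perturbation, linear
    support-vector decoding with bootstrap and false-discovery-rate
    inference, searchlight mapping over electrode grids, independent
    component analysis with permutation scoring of components, and
    frequency-resolved conditional Granger causality via nonparametric
    spectral matrix factorization with permutation thresholds and a
    band-wise directionality statistic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
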