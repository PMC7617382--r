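Package: memland
Title: Pairwise Maximum-Entropy Models and Energy Landscapes for
    Coarse-Grained Neural Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multineuron activity, by exact likelihood gradient descent for small
    systems and pseudo-likelihood maximization for larger ones.  Provides
    the surrounding analysis pipeline: spatial and functional clustering of
    neuron traces into region-level time series, binarization, model
    evaluation by multi-information and structure-function coupling
    (correlation and ROC/AUC against a structural connectivity matrix),
    exhaustive energy-landscape decomposition (local minima, basins of
    attraction, saddle states, disconnectivity structure, energy barriers),
    Metropolis-Hastings simulation of basin-level state transitions, and
    temperature-dependent thermodynamics (specific heat, susceptibility,
    critical temperature, virtual resection).  A synthetic-data generator
    with known ground truth makes every stage testable without external
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pROC,
    MASS,
    withr
Config/testthat/edition: 3
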