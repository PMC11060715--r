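Package: catraces
Title: Single-Cell Calcium Imaging Analysis: Transients, Functional
    Connectivity, and Neural Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, seed-reproducible analysis chain for awake
    two-photon calcium imaging of cortical populations: neuropil-corrected
    dF/F preprocessing with a running-percentile baseline, detection of
    statistically significant calcium transients against a robust noise
    model, movement-conditioned firing rates, functional connectivity
    graphs validated by a stationary block-bootstrap null, overlapping
    neural-assembly detection by PCA with oblique Promax rotation
    (including merge rules, circular-shift synchrony surrogates, and
    hypergeometric activation significance), widefield sensory-evoked
    response-map metrics, and behavioral kinematics for beam-walking and
    string-pull tasks. A synthetic-data generator plants known assemblies,
    movement modulation, widefield response blobs, and paw paths so every
    stage is testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    jsonlite,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
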