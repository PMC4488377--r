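Package: hublesion
Title: Task-Evoked Connectivity Hubs and Simulated-Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying functional hubs in task-evoked brain
    networks and predicting the behavioural impact of focal lesions.
    Estimates directed psychophysiological-interaction (PPI) connectivity
    from region-of-interest BOLD time series via hemodynamic deconvolution
    and reconvolution, aggregates sessions into a group z-matrix with FDR
    thresholding, computes weighted and binary directed betweenness
    centrality with pooled randomization nulls, and implements a
    simulated-lesion method: leave-one-session-out RBF support-vector
    classification of high versus low performance sessions from
    connectivity patterns, with node-deleted feature sets and a
    random-edge-deletion null on the arcsine scale. A synthetic-data
    module generates task designs, AR(1)-noise BOLD with planted
    condition-dependent coupling, and session cohorts with
    performance-linked class structure, so that the whole pipeline is
    testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    jsonlite,
    knitr,
    rmarkdown,
    withr,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
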