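Package: multiscan
Title: Simultaneous Detection and Evaluation of Multiple Spatial Disease Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects multiple spatial disease clusters simultaneously by
    combining spatial scan statistics with a multiple-cluster Poisson
    generalized linear model. Candidate clusters are generated by a
    sequential secondary-cluster scan procedure (circular or flexibly
    shaped windows), the number of clusters is selected with a
    marginal-likelihood information criterion and its relative-difference
    statistic, and the significance of the selected multiple-cluster model
    as a whole is assessed by Monte Carlo testing. Includes readers for
    SaTScan-style coordinate, case and population files, indirect
    standardization of expected counts, and a synthetic-map simulation
    toolkit for power, sensitivity and positive-predictive-value studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
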