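Package: penbayes
Title: Layered Ensemble Learning of Bayesian Network Structure from Partitioned Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Learns discrete Bayesian network structure from large tabular
    datasets with a three-layered weighted-voting ensemble. Includes BDeu
    scoring, hill-climbing, tabu-search and max-min hill-climbing base
    learners, a greedy doubling estimator of the appropriate learning size
    (the smallest data slice on which learned-structure statistics
    stabilise), a weighted-adjacency-matrix structure ensemble, forward
    sampling from ground-truth networks for simulation studies, and
    structural Hamming distance evaluation. Results carry tidy() and
    glance() methods and ggplot2 autoplot() views.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
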