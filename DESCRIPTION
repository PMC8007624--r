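Package: oifnet
Title: Optimal Information Flow Networks from Ecological Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Infers directed predictive-causality networks from multivariate
    abundance time series. Implements transfer-entropy network inference with
    mutual-information-optimal time delays (the optimal information flow
    approach), alongside linear correlation and convergent cross mapping
    (simplex projection on lagged-coordinate embeddings) as comparators.
    Includes benchmark generators (coupled logistic maps, a seasonal
    multispecies community with planted interactions, Gaussian vector
    autoregressions with closed-form transfer entropy), time-resolved
    dynamical networks at a fixed inference resolution, and effective
    alpha-diversity prediction with threshold optimization against taxonomic
    alpha-diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
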