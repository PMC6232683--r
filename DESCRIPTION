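Package: bpllda
Title: Path-Based Prediction of lncRNA-Disease Associations in a
    Heterogeneous Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts long noncoding RNA (lncRNA)-disease associations by
    scoring bounded-length simple paths in a heterogeneous network built
    from known associations, integrated lncRNA similarity, and integrated
    disease similarity. Implements lncRNA functional similarity from
    disease semantic similarity, Gaussian interaction-profile kernel
    similarities with fallback integration, thresholded network assembly,
    decay-weighted path scoring via depth-first enumeration, global and
    local leave-one-out cross-validation with ROC/AUC, precision-by-score
    binning, parameter sweeps, a kernel ablation driver, and a synthetic
    data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
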