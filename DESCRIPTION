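Package: rsapart
Title: Representational Similarity Analysis with Variance Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representational similarity analysis (RSA) of brain and
    behavioral data: construction and comparison of representational
    dissimilarity matrices (RDMs), cross-validated Mahalanobis (crossnobis)
    distances with multivariate noise normalization, commonality-analysis
    variance partitioning across three model RDMs, nonparametric group
    statistics (signed-rank tests, FDR, noise ceilings, split-group
    reproducibility permutation tests), volumetric searchlight mapping with
    threshold-free cluster enhancement (TFCE) and sign-flip permutation
    inference, decorrelated stimulus-set selection with an odds-algorithm
    stopping rule, and synthetic-data generators with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
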