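Package: matekin
Title: Pedigree Kinship and Inbreeding-Avoidance Analyses for Social Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying inbreeding avoidance in plural-breeding social
    mammals. Computes exact pedigree-based kinship, relatedness and inbreeding
    coefficients (with a Monte Carlo gene-dropping validator), runs constrained
    permutation tests for non-random mate pairing and mate-guarding, compares
    mate-guard and extra-pair-sire relatedness with paired t-tests, fits
    mixed-model tests of inbreeding depression and mate-guard success, and
    provides a forward-time simulator of a bi-philopatric, cooperatively
    breeding population so that every stage of the pipeline can be validated
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    lme4,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
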