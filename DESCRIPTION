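Package: geneticEnsemble
Title: Genetic Ensemble Search for Gene-Gene and Gene-Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene-gene and gene-environment interactions in
    case-control SNP genotype data by combining a genetic-algorithm wrapper
    with an ensemble of categorical classifiers (gain-ratio decision tree,
    KStar, and k-nearest-neighbour with k = 1, 3, 5). Candidate factor
    subsets are scored by a weighted combination of per-classifier balanced
    accuracy (blocking), majority-voting balanced accuracy, and double-fault
    ensemble diversity; best subsets collected over many restarts are ranked
    combinatorially into frequency-scored factor combinations. Includes a
    two-locus purely epistatic penetrance-model simulator with target
    heritability and no marginal effects, and evaluation statistics for
    detection power, false discovery rate and true positive rate at rank or
    frequency cutoffs, and the degree of complementarity and joint power of
    multiple interaction detectors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    rpart
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
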