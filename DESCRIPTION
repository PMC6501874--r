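Package: dupsel
Title: Selection Inference for Duplicated Gene Families from Codon Alignments
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the selective history of duplicated genes from
    in-frame codon alignments and population samples of alleles. Implements
    codon substitution models (M0 and the branch-site model A), maximum-likelihood
    fitting by Felsenstein pruning, branch-site likelihood-ratio tests for episodic
    positive selection with Holm-Bonferroni correction, empirical-Bayes site-class
    posteriors, marginal ancestral codon reconstruction under constrained model
    suites, McDonald-Kreitman tests with Nei-Gojobori pathway counting and
    Jukes-Cantor distance correction (including conservative min-max aggregation
    over ancestral-reconstruction suites), a decision-table classifier of
    duplicate-gene retention modes (neofunctionalization, escape from adaptive
    conflict, concerted neofunctionalization, subfunctionalization), and seeded
    simulators of codon alignments and within-species haplotype samples for
    calibration and power studies.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
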