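Package: tmecrossmap
Title: Cross-Species Tumor Microenvironment Comparison via Consensus NMF
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machinery for comparing tumor microenvironments across species:
    consensus non-negative matrix factorization (cNMF) discovery of gene
    expression programs with cophenetic-correlation rank selection and
    outlier-pruned consensus factors; cross-species program matching by
    top-gene Jaccard indices with Fisher's exact significance; immune
    compartment-frequency harmonization and archetype mapping by cosine
    similarity; cross-compartment ligand expression scaling (TMM/CPM,
    upper-quartile, pseudobulk, ortholog mapping); and coordinated program
    "movement" correlation with Kaplan-Meier survival stratification.
    Includes synthetic-data generators with planted ground truth so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    clue,
    edgeR,
    survival,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
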