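Package: hingecrf
Title: Protein Domain Boundary Prediction via Hinge-Region Profiles and
    Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts protein domain boundaries from sequence using a
    hinge-region strategy: residues are labeled with three states
    (domain, hinge, boundary), per-residue domain/hinge/boundary (DHB)
    frequency profiles are derived from local alignments against a
    database of domain-annotated reference chains, and a linear-chain
    conditional random field over windowed profile and shape-string
    features produces posterior state probabilities that are decoded
    into two-state boundary calls with region-specific decision
    thresholds. Includes the full evaluation suite (sensitivity,
    specificity, accuracy, MCC, weighted score, AUC, bootstrap standard
    errors) and a synthetic generator of annotated sequence families so
    the whole pipeline is testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
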