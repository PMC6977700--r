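Package: ceRNAdys
Title: Detection of Dysregulated Competing Endogenous RNA Triplets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies lncRNA-miRNA-mRNA competing endogenous RNA (ceRNA)
    triplets that become dysregulated between two biological states (for
    example control versus disease, or consecutive disease stages) from
    sample-matched expression profiles. Candidate triplets are assembled in
    the reference state from experimentally supported miRNA-target
    interactions (shared-miRNA hypergeometric test plus signed Pearson
    correlation filters), then scored by combining per-transcript
    differential expression with per-link differential co-expression on a
    standard-normal quantile scale, with empirical significance from a
    permutation null of randomly assembled triplets. Downstream utilities
    cover stage-wise differential expression summaries, fuzzy c-means
    clustering of time-course profiles, co-expression partner extraction,
    gene-set enrichment, and diagnostic/prognostic biomarker panel selection
    via random-forest importance reduction followed by exhaustive
    cross-validated subset search. A seeded synthetic cohort generator with
    planted triplets provides a fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    limma,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    optparse
Config/testthat/edition: 3
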