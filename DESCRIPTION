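Package: vdegscreen
Title: Value-DEG Screening and Regulatory-Module Prioritization for Dual-Condition Time-Course RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing a two-arm (control versus cytokinin-type
    treatment) time-course RNA-seq experiment sharing a single day-0 baseline.
    Implements TPM quantification and expressed-gene filtering, a simplified
    negative-binomial Wald differential-expression test with median-of-ratios
    normalization, the three-contrast (treatment-vs-control, natural-course,
    treatment-course) value-DEG (VDEG) Venn classification with up/down
    direction calls and cross-period sharing, STEM-style model-profile
    clustering of log2 fold-change trajectories with exhaustive permutation
    significance, hypergeometric over-representation tests, tree-ensemble
    regulatory-network inference with promoter motif evidence tiers, and
    fold-change candidate ranking. A seeded synthetic-data generator with
    known truth labels makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
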