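Package: cortexpls
Title: Imaging Transcriptomics of Cortical Atrophy Signatures via Partial Least Squares
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links regional cortical-atrophy signatures to regional gene
    expression. Computes covariate-normalized w-scores of cortical thickness
    against a control cohort, derives per-region case-control t-statistic
    contrast maps, fits single-component partial least squares (PLS1)
    regression of the contrast map on a region-by-gene expression matrix with
    bootstrap standard errors, z-scores and variable importance in projection
    (VIP) for gene selection, relates contrast maps to neurotransmitter
    receptor density maps by spatial correlation and all-subsets dominance
    analysis, and tests gene-set overlap against pathology-related gene lists
    with permutation nulls and hypergeometric over-representation. Includes a
    synthetic-data generator with planted ground truth so the whole pipeline
    is testable without access to cohort MRI or atlas downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
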