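Package: degmeta
Title: Random-Effects Meta-Analysis of Cross-Study Differential Gene
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Combines differential-expression signals from independent
    RNA-seq studies of the same contrast into a single set of
    high-confidence genes. Per-study effect sizes are natural-log
    expression ratios with Welch standard errors; studies are combined
    per gene with the DerSimonian-Laird random-effects model and
    corrected with the Benjamini-Yekutieli procedure. Includes
    cross-study concordance classification of differentially expressed
    genes, median-ratio inter-sample normalization with PCA and Kendall
    rank-correlation diagnostics, principal variance component analysis
    (PVCA) of experimental factors with a Monte-Carlo random-gene-subset
    significance test, Fisher's exact gene-set enrichment, a synthetic
    multi-study data generator with known ground truth, and a pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    fgsea,
    jsonlite,
    stats,
    utils
Suggests:
    DESeq2,
    cluster,
    lme4,
    metafor,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
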