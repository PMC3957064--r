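Package: vtet
Title: Variable Threshold Exact Test for CNV Association from SNP-Array
    Intensities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects disease association of copy number variants (CNVs) in
    short genomic regions directly from SNP-array intensity data, without a
    prior CNV-calling step.  Per-subject evidence that a region harbors a
    deletion or duplication is quantified by the maximum interval scan
    statistic over Log R Ratios (optionally fused with B Allele Frequency
    information), calibrated against a Monte-Carlo null distribution.  A
    variable threshold exact test (VTET) then declares tentative CNV
    carriers at a grid of evidence thresholds, applies Fisher's exact test
    at each, and assesses the minimum p-value by case-control label
    permutation.  Includes a genome-wide segment scan with Bonferroni
    control and QQ diagnostics, and a full simulator of copy-state
    conditional LRR/BAF data for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
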