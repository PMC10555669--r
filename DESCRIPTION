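Package: sumstatQC
Title: Quality Control of GWAS Summary Statistics for Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects metadata errors and analytical issues in genome-wide
    association study (GWAS) summary statistics before they enter two-sample
    Mendelian randomization analyses. The pipeline confirms the identity of the
    effect allele and effect allele frequency columns by comparison with
    catalogue-style top hits and a consensus minor-allele-frequency reference,
    compares reported effect sizes with theoretical expectations derived from
    z-scores, allele frequencies and sample sizes (including an expected log
    odds ratio under an additive logistic model), checks P-value/z-score
    consistency, performs greedy LD clumping with novelty assessment of index
    variants, and aggregates graded conflict flags into a machine-readable QC
    report. A synthetic-data module simulates additive-model summary statistics
    with matching reference panels and injects truth-labelled error modes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    yaml,
    ggplot2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
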