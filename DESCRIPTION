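Package: candgene
Title: Candidate-Gene Expression, Variant Association and Regulatory
    Impact Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for candidate-gene cancer studies that
    combine paired tumor/normal qPCR expression profiling, single-marker
    SNP association of a patient cohort against reference-population
    allele and genotype counts, tumor-versus-normal de novo variant
    screening, and regulatory impact assessment of SNPs.  Implements
    relative expression (2^-ddCt) with Mann-Whitney group comparisons and
    Spearman inter-gene correlation, allelic and genotypic odds ratios
    with Woolf (log-scale) confidence intervals and Haldane-Anscombe
    correction, chi-squared or Fisher association tests with Bonferroni
    adjustment, position-weight-matrix log-odds scoring of SNP effects on
    transcription-factor binding motifs, in-silico restriction-site
    (RFLP) checks with IUPAC degenerate patterns, and canonical microRNA
    seed-match detection.  A synthetic-data module generates all inputs
    with the statistical structure the analyses assume, so the package is
    fully testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
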