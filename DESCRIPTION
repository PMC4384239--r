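Package: regsnp
Title: Regulatory SNP Association Cascade for Paired Tumor/Normal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies regulatory SNPs in paired tumor/normal designs:
    germline SNP alleles whose carrier status predicts per-gene copy-number
    differences or methylation beta-value differences between tumor and
    matched normal tissue, and whose associated modification shows a
    concordant gene-expression change. Implements quantile normalization and
    paired-t differential expression, threshold-based copy-number and
    methylation status calling with a simplified recursive segmentation,
    SNP quality control (minor allele frequency, exact Hardy-Weinberg test,
    Bowker's symmetry test on paired genotypes), a three-stage association
    cascade (Fisher's exact test, linear regression on modification
    magnitude, Kruskal-Wallis) under qualitative and quantitative genotype
    codings, and rank-based expression linkage with concordance
    classification. A synthetic paired-cohort generator with planted effects
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
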