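#!/usr/bin/env Rscript
# SNP quality control: minor allele frequency >= 0.01, exact Hardy-Weinberg
# p > 0.05 (germline calls), plus Bowker's symmetry test of tumor vs normal
# genotypes -- somatic genotype discordance should be negligible in this
# design, and the Bowker p-values audit that assumption.

library(regsnp)

cohort <- read_cohort("results/cohort")
qc <- filter_snps(cohort$genotypes_normal,
                  genotypes_tumor = cohort$genotypes_tumor)

cat(sprintf("retained %d / %d SNPs (MAF >= 0.01, HWE p > 0.05)\n",
            length(qc$retained), nrow(qc$qc)))
cat(sprintf("failures: %d by MAF, %d by HWE\n",
            sum(qc$qc$maf < 0.01, na.rm = TRUE),
            sum(qc$qc$maf >= 0.01 & qc$qc$hwe_p <= 0.05, na.rm = TRUE)))
cat(sprintf("SNPs with Bowker p < 0.05 (tumor/normal asymmetry): %d\n",
            sum(qc$qc$bowker_p < 0.05)))

write.table(qc$qc, "results/snp_qc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
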