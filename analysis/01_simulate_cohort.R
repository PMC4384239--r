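#!/usr/bin/env Rscript
# Build the synthetic paired tumor/normal cohort used by the rest of the
# workflow: 32 pairs, 200 genes, 400 SNPs; three SNPs drive copy-number
# gains in their host genes, two drive methylation gains, and 20 genes
# carry planted expression shifts (majority down-regulated). Ground truth
# is written next to the data so later steps can audit their calls.

library(regsnp)

cnv_eff <- data.frame(snp = 1:3, gene = 1:3, delta = 0.8,
                      model = "qualitative")
met_eff <- data.frame(snp = 4:5, gene = 4:5, delta = 0.5,
                      model = "qualitative")
de_eff <- data.frame(gene = 11:30,
                     shift = c(rep(-1.5, 15), rep(1.5, 5)))

cfg <- simulation_config(
  n_patients = 32, n_genes = 200, n_snps = 400,
  planted_cnv_effects = cnv_eff, planted_meth_effects = met_eff,
  planted_de_effects = de_eff,
  cn_noise_sd = 0.15, beta_noise_sd = 0.08,
  expr_cn_coupling = 1.0, expr_meth_coupling = 2.0,
  expr_noise_sd = 0.3, seed = 20150324)

cohort <- simulate_cohort(cfg)
print(cohort)
write_cohort(cohort, "results/cohort")
write_genotypes_vcf(cohort$genotypes_normal,
                    "results/cohort/genotypes_normal.vcf")
cat("cohort written to results/cohort\n")
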