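#!/usr/bin/env Rscript
# Differential expression on the simulated cohort: joint quantile
# normalization of tumor and normal arrays, gene-wise paired t-tests, and
# selection at p < 1e-9 (stricter than the Bonferroni reference threshold,
# which is printed for comparison).

library(regsnp)

cohort <- read_cohort("results/cohort")
joint <- quantile_normalize(cbind(cohort$expr_tumor, cohort$expr_normal))
nt <- ncol(cohort$expr_tumor)
de <- de_paired_t(joint[, 1:nt], joint[, -(1:nt)], threshold = 1e-9)
sel <- select_de_genes(de, threshold = 1e-9)

cat(sprintf("Bonferroni reference threshold (0.05 / %d genes): %.3g\n",
            nrow(de), bonferroni_threshold(0.05, nrow(de))))
cat(sprintf("selected %d DE genes at p < 1e-9: %d down (%d%%), %d up (%d%%)\n",
            sel$n_selected, sel$n_down, sel$pct_down, sel$n_up, sel$pct_up))

planted <- read.table("results/cohort/truth_planted_de.tsv", header = TRUE)
cat(sprintf("planted DE genes recovered: %d / %d\n",
            sum(planted$gene_id %in% sel$genes$gene_id), nrow(planted)))

dir.create("results", showWarnings = FALSE)
write.table(de, "results/de_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
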