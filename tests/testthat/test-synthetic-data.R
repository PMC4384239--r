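test_that("config validation rejects bad parameters", {
  expect_error(simulation_config(n_patients = 1), "n_patients")
  expect_error(simulation_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(simulation_config(maf_range = c(0.4, 0.1)), "maf_range")
  expect_error(simulation_config(somatic_flip_rate = 1.5), "rates")
  expect_error(simulation_config(
    n_genes = 5, n_snps = 5,
    planted_cnv_effects = data.frame(snp = 9, gene = 1, delta = 1,
                                     model = "qualitative")), "unknown SNP")
  expect_error(simulation_config(
    n_genes = 5, n_snps = 5,
    planted_cnv_effects = data.frame(snp = 1, gene = 1, delta = 1,
                                     model = "dominant")), "model")
})

test_that("degenerate allele frequencies and flip rates behave as limits", {
  cfg <- simulation_config(n_patients = 20, n_genes = 2, n_snps = 5,
                           maf_range = c(0, 0), somatic_flip_rate = 0,
                           seed = 5)
  ch <- simulate_cohort(cfg)
  expect_true(all(ch$genotypes_normal == 0L))
  expect_true(all(ch$genotypes_tumor == 0L))

  cfg2 <- simulation_config(n_patients = 30, n_genes = 2, n_snps = 40,
                            somatic_flip_rate = 0, seed = 6)
  ch2 <- simulate_cohort(cfg2)
  expect_identical(ch2$genotypes_tumor, ch2$genotypes_normal)

  # flip rate 1: every tumor call moves to a different genotype
  cfg3 <- simulation_config(n_patients = 30, n_genes = 2, n_snps = 40,
                            somatic_flip_rate = 1, seed = 6)
  ch3 <- simulate_cohort(cfg3)
  expect_true(all(ch3$genotypes_tumor != ch3$genotypes_normal))
  expect_true(all(ch3$genotypes_tumor %in% 0:2))
})

test_that("germline genotypes follow Hardy-Weinberg proportions", {
  cfg <- simulation_config(n_patients = 10000, n_genes = 1, n_snps = 1,
                           maf_range = c(0.5, 0.5), seed = 9)
  set.seed(cfg$seed)
  g <- simulate_genotypes(cfg)$genotypes_normal
  freq <- tabulate(g + 1L, nbins = 3L) / length(g)
  expected <- c(0.25, 0.5, 0.25)
  se <- sqrt(expected * (1 - expected) / length(g))
  expect_true(all(abs(freq - expected) <= 3 * se))
})

test_that("planted qualitative effects shift carrier means by delta", {
  eff <- data.frame(snp = 1, gene = 1, delta = 0.6, model = "qualitative")
  cfg <- simulation_config(n_patients = 1000, n_genes = 3, n_snps = 2,
                           maf_range = c(0.3, 0.3), planted_cnv_effects = eff,
                           cn_noise_sd = 0.1, seed = 21)
  ch <- simulate_cohort(cfg)
  carrier <- ch$genotypes_normal[1, ] >= 1
  se <- 0.1 / sqrt(sum(carrier))
  expect_lt(abs(mean(ch$cn_diff[1, carrier]) - 0.6), 3 * se)
  se0 <- 0.1 / sqrt(sum(!carrier))
  expect_lt(abs(mean(ch$cn_diff[1, !carrier])), 3 * se0)
  # unplanted genes are pure noise
  expect_lt(abs(mean(ch$cn_diff[2, ])), 3 * 0.1 / sqrt(1000))
})

test_that("null generator and clipping bounds hold", {
  cfg <- simulation_config(n_patients = 8, n_genes = 4, n_snps = 4,
                           cn_noise_sd = 0, beta_noise_sd = 0, seed = 2)
  set.seed(2)
  g <- simulate_genotypes(cfg)
  mod <- simulate_modifications(cfg, g$genotypes_normal)
  expect_true(all(mod$cn_diff == 0))
  expect_true(all(mod$beta_diff == 0))

  eff <- data.frame(snp = 1, gene = 1, delta = 2.0, model = "quantitative")
  cfg2 <- simulation_config(n_patients = 50, n_genes = 2, n_snps = 2,
                            maf_range = c(0.4, 0.5),
                            planted_meth_effects = eff, seed = 3)
  ch2 <- simulate_cohort(cfg2)
  expect_true(all(ch2$beta_diff >= -1 & ch2$beta_diff <= 1))
  expect_true(any(ch2$beta_diff[1, ] == 1))  # clipping engaged
})

test_that("expression couples to modifications with the documented signs", {
  cfg <- simulation_config(n_patients = 1000, n_genes = 5, n_snps = 5,
                           expr_cn_coupling = 1.0, expr_meth_coupling = 0,
                           expr_noise_sd = 0.1, cn_noise_sd = 0.5, seed = 31)
  ch <- simulate_cohort(cfg)
  lr <- ch$expr_tumor - ch$expr_normal
  for (g in 1:5) expect_gt(cor(ch$cn_diff[g, ], lr[g, ]), 0.5)

  # all couplings, shifts and noise zero: tumor equals normal
  cfg0 <- simulation_config(n_patients = 10, n_genes = 3, n_snps = 3,
                            expr_cn_coupling = 0, expr_meth_coupling = 0,
                            expr_noise_sd = 0, seed = 4)
  ch0 <- simulate_cohort(cfg0)
  expect_identical(ch0$expr_tumor, ch0$expr_normal)

  # planted negative DE shift: mean log-ratio negative (down-regulated)
  cfgd <- simulation_config(n_patients = 32, n_genes = 3, n_snps = 3,
                            planted_de_effects = data.frame(gene = 2,
                                                            shift = -1.0),
                            expr_noise_sd = 0.2, cn_noise_sd = 0,
                            beta_noise_sd = 0, seed = 12)
  chd <- simulate_cohort(cfgd)
  expect_lt(mean(chd$expr_tumor[2, ] - chd$expr_normal[2, ]), 0)
})

test_that("a fixed seed reproduces the cohort exactly", {
  eff <- data.frame(snp = 1, gene = 2, delta = 0.5, model = "quantitative")
  cfg <- simulation_config(n_patients = 16, n_genes = 6, n_snps = 9,
                           planted_cnv_effects = eff, missing_rate = 0.05,
                           seed = 77)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(ch1, ch2)
})

test_that("monomorphic planted SNPs are flagged in the truth record", {
  eff <- data.frame(snp = 1, gene = 1, delta = 0.5, model = "qualitative")
  cfg <- simulation_config(n_patients = 10, n_genes = 2, n_snps = 2,
                           maf_range = c(0, 0), planted_cnv_effects = eff,
                           seed = 8)
  expect_warning(ch <- simulate_cohort(cfg), "monomorphic")
  expect_true(ch$truth$planted_cnv$monomorphic[1])
})
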