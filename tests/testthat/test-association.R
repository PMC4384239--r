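test_that("genotype coding implements carrier and allele-count models", {
  row <- c(0L, 1L, 2L, NA)
  qual <- code_genotypes(row, "qualitative")
  expect_equal(qual$codes, c(0L, 1L, 1L, NA))
  quant <- code_genotypes(row, "quantitative")
  expect_equal(quant$codes, c(0L, 1L, 2L, NA))
  # qualitative code is exactly the indicator quantitative >= 1
  set.seed(91)
  g <- sample(c(0:2, NA), 50, replace = TRUE)
  expect_equal(code_genotypes(g, "qualitative")$codes,
               ifelse(is.na(g), NA_integer_,
                      as.integer(code_genotypes(g, "quantitative")$codes >= 1L)))
  # tested allele = major counts major copies
  expect_equal(code_genotypes(row, "quantitative", "major")$codes,
               c(2L, 1L, 0L, NA))
  expect_equal(code_genotypes(row, "qualitative", "major")$codes,
               c(1L, 1L, 0L, NA))
  expect_true(code_genotypes(rep(0L, 5), "qualitative")$untestable)
  expect_false(code_genotypes(row, "qualitative")$untestable)
})

test_that("contingency tables tally patients by code level and status", {
  tab <- build_contingency(c(1L, 1L, 0L, 0L), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(unname(tab), matrix(1L, 2, 2))
  # qualitative -> 2 rows; quantitative with all levels -> 3 rows
  codes3 <- c(0L, 0L, 1L, 1L, 2L, 2L)
  mod3 <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  tab3 <- build_contingency(codes3, mod3)
  expect_equal(dim(tab3), c(3L, 2L))
  # conservation: cells sum to patients with both defined
  codes_na <- c(0L, 1L, NA, 1L)
  mod_na <- c(TRUE, NA, TRUE, FALSE)
  expect_equal(sum(build_contingency(codes_na, mod_na)), 2)
  expect_error(build_contingency(c(NA_integer_), c(TRUE)), "no patient")
})

test_that("Fisher exact p matches brute-force enumeration on hand-picked tables", {
  # degenerate margins admit one table
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2)), 1)
  expect_equal(fisher_exact(matrix(c(2, 5, 0, 0), 2, 2)), 1)
  t22 <- matrix(c(3, 1, 1, 3), 2, 2)
  expect_equal(fisher_exact(t22), oracle_fisher(t22), tolerance = 1e-12)
  t32 <- matrix(c(1, 2, 3, 2, 1, 0), 3, 2)
  expect_equal(fisher_exact(t32), oracle_fisher(t32), tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2, 2)), "integer")
  expect_error(fisher_exact(matrix(1, 4, 2)), "rows")
})

test_that("Fisher exact p agrees with stats::fisher.test on random tables", {
  set.seed(92)
  for (i in 1:100) {
    t22 <- matrix(rpois(4, 4), 2, 2)
    expect_equal(fisher_exact(t22), fisher.test(t22)$p.value,
                 tolerance = 1e-9)
    t32 <- matrix(rpois(6, 3), 3, 2)
    if (sum(t32) == 0) next
    expect_equal(fisher_exact(t32), fisher.test(t32)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("regression stage reproduces closed-form least squares", {
  codes <- c(0L, 1L, 2L, 0L, 1L, 2L)
  mags <- c(0.0, 0.3, 0.6, 0.1, 0.4, 0.5)
  res <- regression_stage(codes, mags)
  # independent normal-equations oracle
  x <- as.numeric(codes); y <- mags; n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  resid <- y - (mean(y) - slope * mean(x)) - slope * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t_stat <- slope / se
  expect_equal(res$slope, slope)
  expect_equal(res$p_value, 2 * pt(-abs(t_stat), n - 2))
  expect_equal(res$flag, "ok")
})

test_that("regression stage flags degenerate responses", {
  expect_equal(regression_stage(c(0L, 1L, 2L, 1L), rep(0.4, 4)),
               list(slope = 0, p_value = 1, n = 4, flag = "constant_response"))
  expect_warning(
    pf <- regression_stage(c(0L, 1L, 2L, 0L), c(0, 0.5, 1.0, 0)),
    "zero residual variance")
  expect_equal(pf$p_value, 0)
  expect_equal(pf$flag, "perfect_fit")
  expect_equal(pf$slope, 0.5)
  expect_error(regression_stage(c(1L, 1L, 1L), c(1, 2, 3)), "constant")
  expect_error(regression_stage(c(0L, 1L), c(1, 2)), "at least 3")
})

test_that("Kruskal-Wallis matches the hand rank-sum computation", {
  res <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7
  H <- 12 / 42 * (36 / 3 + 225 / 3) - 21
  expect_equal(res$statistic, H)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(H, 1, lower.tail = FALSE))
  expect_equal(kruskal_wallis(list(rep(2, 4), rep(2, 3))),
               list(statistic = 0, p_value = 1, df = 1L))
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
  # empty groups are dropped before the test
  expect_equal(kruskal_wallis(list(c(1, 2, 3), numeric(0), c(4, 5, 6)))$df, 1)
})

test_that("two-group Kruskal-Wallis equals normal-approximation rank-sum", {
  set.seed(93)
  for (i in 1:50) {
    x <- rnorm(10); y <- rnorm(12)
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    expect_equal(p_kw, p_w, tolerance = 1e-10)
  }
})

test_that("cascade finds nothing when statuses have no contrast", {
  ch <- make_planted_cohort(seed = 94)
  calls <- call_modifications(ch)
  calls$cnv_status[] <- "neutral"
  calls$meth_status[] <- "unchanged"
  rec <- run_cascade(ch, calls = calls)
  expect_equal(nrow(rec), 0)
  skipped <- attr(rec, "skipped")
  expect_true(all(skipped$reason %in%
                    c("no_status_contrast", "untestable_code",
                      "gene_not_in_cohort")))
})

test_that("a strong planted effect survives all three stages, verified independently", {
  ch <- make_planted_cohort(seed = 95, delta = 0.8, n_planted = 1,
                            noise = 0.15)
  rec <- run_cascade(ch)
  hit <- rec[rec$snp_id == "snp0001" & rec$direction == "amplification" &
               rec$model == "qualitative", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$stage_passed, "kw")

  # recompute the three stages with reference implementations
  codes <- code_genotypes(ch$genotypes_normal["snp0001", ], "qualitative")$codes
  amp <- call_cnv_status(ch$cn_diff["gene0001", ]) == "amplified"
  tab <- build_contingency(codes, amp)
  expect_equal(hit$fisher_p, fisher.test(tab)$p.value, tolerance = 1e-9)
  fit <- summary(lm(ch$cn_diff["gene0001", ] ~ codes))$coefficients
  expect_equal(hit$regression_p, fit["codes", "Pr(>|t|)"])
  expect_equal(hit$regression_slope, fit["codes", "Estimate"])
  kt <- kruskal.test(ch$cn_diff["gene0001", ], factor(codes))
  expect_equal(hit$kw_p, kt$p.value)
  expect_true(hit$fisher_p < 0.01 && hit$regression_p < 0.01 &&
                hit$kw_p < 0.01)
})

test_that("stage p-values appear only after the previous stage passed", {
  ch <- make_planted_cohort(seed = 96, delta = 0.5, n_planted = 5,
                            noise = 0.25)
  rec <- run_cascade(ch)
  expect_true(all(is.na(rec$regression_p[rec$stage_passed == "none"])))
  expect_true(all(!is.na(rec$regression_p[rec$stage_passed != "none"])))
  expect_true(all(is.na(rec$kw_p[rec$stage_passed %in% c("none", "fisher")])))
  expect_true(all(!is.na(rec$kw_p[rec$stage_passed %in% c("regression", "kw")])))
})

test_that("survivor counts are monotone non-increasing across stages", {
  ch <- make_planted_cohort(seed = 97, delta = 0.6, n_planted = 8,
                            noise = 0.2, n_genes = 30, n_snps = 60)
  s <- stage_summary(run_cascade(ch))
  expect_true(all(s$fisher >= s$regression))
  expect_true(all(s$regression >= s$kw))
})
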