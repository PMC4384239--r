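---
title: "The regulatory-SNP association cascade: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The regulatory-SNP association cascade: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsnp)
```

## The problem and the model

In a paired tumor/normal design, every patient contributes two tissues
profiled on three platforms: genome-wide SNP genotypes, gene-level DNA copy
number, and gene-level promoter methylation (beta values), alongside
expression arrays. A *regulatory SNP* is a germline variant whose genotype
predicts a somatic modification at a gene — a copy-number difference
`CN_dif = CN_tumor − CN_normal` or a beta difference
`Δβ = β_tumor − β_normal` — and whose associated modification shows a
concordant downstream expression change. Because germline genotypes are
fixed before tumorigenesis, such variants are candidate hereditary drivers
rather than consequences of the tumor.

The pipeline tests this in five stages:

1. **Differential expression.** Tumor and normal arrays are jointly
   quantile-normalized and each gene is tested with a paired t-test
   (`t = mean(d) / (sd(d)/√n)`, `d` the per-patient log2 difference,
   `n − 1` df). The default selection threshold `p < 1e-9` is deliberately
   stricter than the Bonferroni reference `0.05/m`.
2. **Modification calls.** Per gene and patient,
   `CN_dif ≥ 0.3` is amplified, `CN_dif ≤ −0.3` deleted;
   `Δβ ≥ 0.25` hypermethylated, `Δβ ≤ −0.25` hypomethylated. Bounds are
   inclusive, following the "at least" convention of the thresholds.
3. **SNP QC.** Germline (normal-tissue) genotypes are retained at
   MAF ≥ 0.01 and exact Hardy-Weinberg p > 0.05. Bowker's symmetry test on
   the paired 3×3 tumor-vs-normal genotype table audits the assumption
   that somatic genotype discordance is negligible.
4. **Association cascade.** Each retained SNP is coded two ways against
   its host gene: *qualitative* (carrier of the tested allele, 0/1) and
   *quantitative* (allele count, 0/1/2). For each modification direction,
   a code-by-status contingency table (2×2 or 3×2) is tested with Fisher's
   exact test; survivors proceed to an OLS regression of the modification
   magnitude on the code (t-test on the slope); survivors of that proceed
   to a Kruskal-Wallis test across code groups. Each stage gates at
   `p < 0.01`.
5. **Expression linkage.** For cascade survivors, per-patient expression
   log-ratios are compared across the SNP grouping with a rank test
   (`p < 0.05`), and the sign of the carrier-group median is compared with
   the direction expected from the modification: amplification and
   hypomethylation should raise expression, deletion and hypermethylation
   lower it. Agreement is concordant (`+`), disagreement discordant (`−`).

## What the synthetic cohort emulates

Real microarray cohorts of this design are not redistributable, so a
generator ([simulate_cohort()]) provides ground truth for every stage. It
emulates:

* 32 tumor/normal pairs (the size this design was built around);
* germline genotypes drawn per SNP from Hardy-Weinberg proportions at a
  MAF sampled uniformly from (0.05, 0.5) by default — comfortably above
  the QC floor of 0.01 so QC attrition reflects test calibration, not
  boundary effects;
* rare somatic genotype discordance: each tumor call moves to a uniformly
  chosen different genotype with probability 0.001, enough to exercise
  Bowker's test without violating the germline-stability assumption;
* planted modification effects: a gene's `CN_dif` (or `Δβ`) is the sum of
  `δ × code` over its planted driver SNPs plus Gaussian noise
  (`cn_noise_sd = 0.2`, `beta_noise_sd = 0.1` by default); `Δβ` is clipped
  to [−1, 1] rather than passed through a logistic link, keeping `δ`
  interpretable in beta units;
* expression coupled to the modifications with the concordance sign
  convention: log-ratio `= 1.0 × CN_dif − 1.0 × Δβ + DE shift + noise`
  (`expr_noise_sd = 0.5`, baseline log2 intensity 8), plus planted
  differentially expressed genes, majority down-regulated in the bundled
  analysis scripts.

Gaussian noise is an assumption of the generator, not a claim about any
particular platform. The generator does **not** model probe-level
intensities, linkage disequilibrium between SNPs, tumor purity or
clonality; passing tests therefore demonstrate the statistical machinery
and its calibration, not robustness to those real-data complications.

## Numerical and design choices

* **Fisher's exact test** is computed by full margin-preserving
  enumeration (hypergeometric for 2×2, Freeman–Halton for 3×2), with ties
  in table probabilities resolved at a relative tolerance of `1e-7`. This
  matches `stats::fisher.test` to ~1e-14 on random tables; the in-package
  version exists so the two-sided definition and tie handling are pinned
  rather than inherited.
* **HWE exact test**: conditional enumeration over heterozygote counts
  given the minor-allele total, two-sided by summing configurations no
  more probable than the observed (same `1e-7` tie tolerance). The test is
  conservative at n = 32 by discreteness — its measured rejection rate at
  0.05 is ≈ 0.025 — which is the standard behavior of the exact test, and
  the reason the chi-square approximation is not the default.
* **Kruskal–Wallis vs Wilcoxon.** The cascade's third stage uses the
  tie-corrected Kruskal-Wallis statistic with a chi-square p-value; at two
  groups this equals the two-sided normal-approximation rank-sum p without
  continuity correction (verified to 1e-14 in the tests). The *expression*
  rank test instead uses `stats::wilcox.test` defaults — exact when sample
  sizes permit and there are no ties — because with 32 patients split by
  carrier status exact p-values are both available and preferable.
* **Regression stage.** The model form is simple OLS of magnitude on the
  code with a slope t-test. Degenerate inputs are flagged, not dropped: a
  constant response reports slope 0, p = 1; a perfect fit (zero residual
  variance) reports p = 0 with a warning.
* **Status pooling.** Testing amplification, the contingency columns are
  (amplified, not-amplified) with neutral and deleted pooled; symmetric
  for the other three directions. Pairs whose status vector lacks both a
  modified and an unmodified patient are skipped and logged, since Fisher
  would be degenerate.
* **Tested allele** defaults to the minor allele; both codings of the
  major allele are available since carrier status is symmetric in
  principle.
* **Segmentation** (for marker-level copy-number input) is recursive
  binary splitting: the candidate breakpoint with the smallest Welch
  t-test p-value is accepted only if both flanks hold ≥ 100 markers,
  p ≤ 0.001, and |Δmean|/pooled SD ≥ 0.3 (the signal-to-noise ratio is
  operationalized as that ratio; it is not otherwise defined by the
  criteria). This is a deliberately simple stand-in for commercial
  segmentation engines: it honors the published acceptance criteria, not
  any vendor statistic. Two consequences are worth knowing. First,
  recursive splitting applies no multiple-testing correction across
  candidate positions, so with permissive `min_markers` it can over-split
  long noisy stretches; the guaranteed property (and the tested one) is
  that planted breakpoints are localized to ±2 markers. Second, the
  minimum-marker rule prevents *isolating* events shorter than
  `min_markers`, but an under-length event embedded in a very long
  baseline can still surface inside a longer mixed segment — any
  segmentation honoring only these three criteria behaves this way.
* **Coordinates** are 0-based half-open throughout; strand is ignored
  (copy number and methylation differences are strand-free). Gene-level
  aggregation over segments is a length-weighted mean of segment means.
* **Expression scale.** The paired t-test is applied to (normalized) log2
  intensities; this is configurable but assumed, as the analysis scale is
  not dictated by the procedure itself.

## Calibration facts the tests establish

On fully null cohorts (no planted effects, 32 patients, 500 genes, 2,000
SNPs, 20 seeds) the Fisher stage passes ≈ 0.1% of tests at the 1%
threshold — conservative, as expected for an exact test on small discrete
tables. Planted qualitative copy-number effects of δ = 0.8 against noise
SD 0.15 are recovered through the full cascade for ≈ 94% of planted SNPs,
with ≈ 93% of detections labeled concordant `+`, and detection power is
non-decreasing in δ over {0.2, 0.4, 0.6, 0.8}.

One subtlety is documented rather than hidden: in a null cohort whose
expression is still *coupled* to the (noise) modification layers — the
generator's default, because that coupling is the biology the pipeline
assumes — a chance cascade survivor reflects a real noise excursion in
`CN_dif`, and expression genuinely follows it. The expression-linkage
stage is therefore not an independent 5% filter conditional on cascade
survival; across 20 null seeds a handful of full-chain false positives
appear (typically 0–1 per seed). With the coupling set to zero the linkage
stage is calibrated (≤ 5% false linkage of planted modification SNPs),
which the test suite verifies separately.

## Problem sizes

The bundled analysis scripts use 32 pairs, 200 genes and 400 SNPs; the
calibration suites use 500 genes × 2,000 SNPs per null seed, 10,000 SNPs
for HWE calibration, and exhaustive Fisher enumeration over all 2×2 and
3×2 tables with total ≤ 20. These sizes give stable rates (binomial SEs
well below the margins asserted) while keeping the whole suite fast on a
single CPU.

## Known limitations

* Host-gene pairing only: a SNP is tested against the gene it is assigned
  to, not against all modified genes genome-wide.
* Raw per-stage thresholds replicate the original procedure;
  Benjamini–Hochberg across SNP–gene pairs would be the modern choice and
  is easy to add downstream of the emitted records, but is off by default.
* No covariate adjustment, trend tests, or LD-aware grouping.
* The contingency-table row/column convention (code levels × modified
  status) is an inference from the "2×2 or 3×2" design; the pooling of
  non-modified categories is configurable in principle but fixed here.
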