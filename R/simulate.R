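# Synthetic paired tumor/normal cohort with planted regulatory-SNP effects.
# Genotypes are coded as minor-allele counts: 0 = hom major, 1 = het,
# 2 = hom minor, NA = missing call.

#' Configuration for the synthetic paired-cohort generator
#'
#' Collects every generator parameter with validation. The defaults emulate
#' the study design the pipeline targets: 32 tumor/normal pairs, germline
#' genotypes in Hardy-Weinberg equilibrium, rare somatic genotype
#' discordance, SNP-allele-driven shifts in per-gene copy-number difference
#' (`CN_dif`, tumor minus normal) and methylation beta difference, and
#' expression log-ratios coupled positively to copy number and negatively to
#' methylation.
#'
#' @param n_patients Number of tumor/normal pairs (>= 2).
#' @param n_genes,n_snps Number of genes and SNPs.
#' @param maf_range Length-2 numeric, minor-allele-frequency range in
#'   `[0, 0.5]` from which each SNP's MAF is drawn uniformly. A zero lower
#'   bound is allowed as a degenerate case (monomorphic SNPs); QC filters
#'   such SNPs downstream.
#' @param somatic_flip_rate Per-call probability that a tumor genotype moves
#'   to a uniformly chosen different genotype (rare somatic discordance).
#' @param missing_rate Per-call probability of a missing genotype.
#' @param planted_cnv_effects,planted_meth_effects Data frames with columns
#'   `snp`, `gene` (integer indices), `delta` (effect size in copy-number or
#'   beta units per code unit) and `model` (`"qualitative"` carrier indicator
#'   or `"quantitative"` allele count). `NULL` for none.
#' @param cn_noise_sd,beta_noise_sd Gaussian noise SD of the copy-number
#'   difference and beta difference layers.
#' @param expr_cn_coupling Expression log-ratio units per copy-number unit
#'   (applied with positive sign).
#' @param expr_meth_coupling Expression log-ratio units per beta unit
#'   (applied with negative sign: promoter methylation represses).
#' @param planted_de_effects Data frame with columns `gene` (integer index)
#'   and `shift` (log2-ratio shift added to tumor expression). `NULL` for
#'   none.
#' @param expr_noise_sd Gaussian noise SD of expression values (log2 scale).
#' @param baseline_log2 Mean baseline log2 intensity of normal tissue.
#' @param seed Integer seed; fixes the whole cohort bit-for-bit.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
simulation_config <- function(n_patients = 32L,
                              n_genes = 100L,
                              n_snps = 200L,
                              maf_range = c(0.05, 0.5),
                              somatic_flip_rate = 0.001,
                              missing_rate = 0,
                              planted_cnv_effects = NULL,
                              planted_meth_effects = NULL,
                              cn_noise_sd = 0.2,
                              beta_noise_sd = 0.1,
                              expr_cn_coupling = 1.0,
                              expr_meth_coupling = 1.0,
                              planted_de_effects = NULL,
                              expr_noise_sd = 0.5,
                              baseline_log2 = 8,
                              seed = 1L) {
  stopifnot(length(n_patients) == 1L, length(n_genes) == 1L,
            length(n_snps) == 1L)
  if (n_patients < 2L) stop("n_patients must be >= 2")
  if (n_genes < 1L || n_snps < 1L) stop("need at least one gene and one SNP")
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1L] > maf_range[2L] ||
      maf_range[1L] < 0 || maf_range[2L] > 0.5) {
    stop("maf_range must be an increasing pair within [0, 0.5]")
  }
  for (p in c(somatic_flip_rate, missing_rate)) {
    if (!is.finite(p) || p < 0 || p > 1) stop("rates must be in [0, 1]")
  }
  for (s in c(cn_noise_sd, beta_noise_sd, expr_noise_sd)) {
    if (!is.finite(s) || s < 0) stop("noise SDs must be non-negative")
  }
  planted_cnv_effects <- validate_effects(planted_cnv_effects, n_snps, n_genes)
  planted_meth_effects <- validate_effects(planted_meth_effects, n_snps, n_genes)
  if (!is.null(planted_de_effects)) {
    stopifnot(is.data.frame(planted_de_effects),
              all(c("gene", "shift") %in% names(planted_de_effects)))
    if (any(planted_de_effects$gene < 1L | planted_de_effects$gene > n_genes))
      stop("planted DE effect references an unknown gene")
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_genes = as.integer(n_genes),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    somatic_flip_rate = somatic_flip_rate,
    missing_rate = missing_rate,
    planted_cnv_effects = planted_cnv_effects,
    planted_meth_effects = planted_meth_effects,
    cn_noise_sd = cn_noise_sd,
    beta_noise_sd = beta_noise_sd,
    expr_cn_coupling = expr_cn_coupling,
    expr_meth_coupling = expr_meth_coupling,
    planted_de_effects = planted_de_effects,
    expr_noise_sd = expr_noise_sd,
    baseline_log2 = baseline_log2,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

validate_effects <- function(eff, n_snps, n_genes) {
  if (is.null(eff)) return(NULL)
  stopifnot(is.data.frame(eff),
            all(c("snp", "gene", "delta", "model") %in% names(eff)))
  if (any(eff$snp < 1L | eff$snp > n_snps))
    stop("planted effect references an unknown SNP")
  if (any(eff$gene < 1L | eff$gene > n_genes))
    stop("planted effect references an unknown gene")
  if (!all(eff$model %in% c("qualitative", "quantitative")))
    stop("effect model must be 'qualitative' or 'quantitative'")
  eff
}

snp_ids <- function(n) sprintf("snp%04d", seq_len(n))
gene_ids <- function(n) sprintf("gene%04d", seq_len(n))
patient_ids <- function(n) sprintf("P%02d", seq_len(n))

#' Simulate germline and tumor genotype matrices
#'
#' Normal-tissue genotypes are drawn per SNP from Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) at a minor-allele frequency sampled uniformly from
#' `config$maf_range`. Tumor genotypes equal the germline calls except for
#' independent somatic "flips" at `config$somatic_flip_rate`, where a flip
#' moves the call to one of the two other genotypes uniformly. Missing calls
#' are planted independently in each tissue at `config$missing_rate`.
#'
#' Uses the current RNG state; [simulate_cohort()] seeds it from
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return A list with `genotypes_normal` and `genotypes_tumor` (SNP x
#'   patient integer matrices of minor-allele counts, NA = missing) and
#'   `maf` (the per-SNP frequency each row was drawn at).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_s <- config$n_snps
  n_p <- config$n_patients
  maf <- runif(n_s, config$maf_range[1L], config$maf_range[2L])
  probs <- cbind((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  u <- matrix(runif(n_s * n_p), n_s, n_p)
  gn <- (u >= probs[, 1L]) + (u >= probs[, 1L] + probs[, 2L])
  storage.mode(gn) <- "integer"

  gt <- gn
  flips <- matrix(runif(n_s * n_p) < config$somatic_flip_rate, n_s, n_p)
  if (any(flips)) {
    idx <- which(flips)
    # move to a uniformly chosen different genotype
    step <- sample(1:2, length(idx), replace = TRUE)
    gt[idx] <- (gt[idx] + step) %% 3L
  }
  if (config$missing_rate > 0) {
    gn[matrix(runif(n_s * n_p) < config$missing_rate, n_s, n_p)] <- NA_integer_
    gt[matrix(runif(n_s * n_p) < config$missing_rate, n_s, n_p)] <- NA_integer_
  }
  dimnames(gn) <- dimnames(gt) <- list(snp_ids(n_s), patient_ids(n_p))
  names(maf) <- rownames(gn)
  list(genotypes_normal = gn, genotypes_tumor = gt, maf = maf)
}

# Code one genotype row under a model; used by both the generator (to apply
# planted effects) and the association stage (exported there with QC checks).
genotype_code <- function(genotypes, model, tested_allele = "minor") {
  g <- if (tested_allele == "minor") genotypes else 2L - genotypes
  if (model == "qualitative") {
    code <- as.integer(g >= 1L)
  } else {
    code <- as.integer(g)
  }
  code[is.na(genotypes)] <- NA_integer_
  code
}

#' Simulate modification layers driven by planted SNP effects
#'
#' For each gene, the copy-number difference `CN_dif` (tumor minus normal)
#' is the sum of its planted effects -- effect size times the driving SNP's
#' code under the effect's model -- plus Gaussian noise; genes with no
#' planted effect are pure noise. The beta-difference layer is generated the
#' same way and then clipped to `[-1, 1]`. Planted SNPs that happen to be
#' monomorphic in the realized cohort contribute no contrast; they are
#' flagged in the returned `truth` tables.
#'
#' @param config A [simulation_config()].
#' @param genotypes_normal Germline genotype matrix from
#'   [simulate_genotypes()].
#' @return List with `cn_diff` and `beta_diff` (gene x patient matrices) and
#'   `truth` (the planted effect tables with a `monomorphic` flag column).
#' @export
simulate_modifications <- function(config, genotypes_normal) {
  stopifnot(inherits(config, "simulation_config"))
  n_g <- config$n_genes
  n_p <- config$n_patients
  pids <- colnames(genotypes_normal)

  layer <- function(effects, noise_sd) {
    m <- matrix(rnorm(n_g * n_p, 0, noise_sd), n_g, n_p,
                dimnames = list(gene_ids(n_g), pids))
    if (is.null(effects)) return(list(m = m, truth = NULL))
    effects$monomorphic <- FALSE
    for (i in seq_len(nrow(effects))) {
      row <- genotypes_normal[effects$snp[i], ]
      code <- genotype_code(row, effects$model[i])
      if (length(unique(code[!is.na(code)])) < 2L) {
        effects$monomorphic[i] <- TRUE
        warning(sprintf("planted SNP %s is monomorphic in the realized cohort",
                        rownames(genotypes_normal)[effects$snp[i]]))
      }
      contrib <- effects$delta[i] * code
      contrib[is.na(contrib)] <- 0
      m[effects$gene[i], ] <- m[effects$gene[i], ] + contrib
    }
    list(m = m, truth = effects)
  }

  cn <- layer(config$planted_cnv_effects, config$cn_noise_sd)
  be <- layer(config$planted_meth_effects, config$beta_noise_sd)
  be$m <- pmin(pmax(be$m, -1), 1)
  list(cn_diff = cn$m, beta_diff = be$m,
       truth = list(planted_cnv = cn$truth, planted_meth = be$truth))
}

#' Simulate paired expression matrices coupled to the modification layers
#'
#' Per gene and patient the expression log-ratio is
#' `expr_cn_coupling * CN_dif - expr_meth_coupling * beta_dif + DE shift +
#' noise`; normal-tissue expression is baseline log2 intensity plus noise and
#' tumor expression is normal plus the log-ratio. The sign convention
#' (copy-number gain raises expression, methylation gain represses it)
#' matches the concordance classification in [classify_concordance()].
#'
#' @param config A [simulation_config()].
#' @param cn_diff,beta_diff Gene x patient matrices from
#'   [simulate_modifications()].
#' @return List with `expr_tumor` and `expr_normal` (gene x patient, log2
#'   scale).
#' @export
simulate_expression <- function(config, cn_diff, beta_diff) {
  stopifnot(inherits(config, "simulation_config"),
            identical(dim(cn_diff), dim(beta_diff)))
  n_g <- nrow(cn_diff)
  n_p <- ncol(cn_diff)
  shift <- numeric(n_g)
  if (!is.null(config$planted_de_effects)) {
    shift[config$planted_de_effects$gene] <- config$planted_de_effects$shift
  }
  log_ratio <- config$expr_cn_coupling * cn_diff -
    config$expr_meth_coupling * beta_diff + shift +
    matrix(rnorm(n_g * n_p, 0, config$expr_noise_sd), n_g, n_p)
  expr_normal <- config$baseline_log2 +
    matrix(rnorm(n_g * n_p, 0, config$expr_noise_sd), n_g, n_p,
           dimnames = dimnames(cn_diff))
  expr_tumor <- expr_normal + log_ratio
  list(expr_tumor = expr_tumor, expr_normal = expr_normal)
}

#' Generate a complete synthetic paired cohort
#'
#' Seeds the RNG from `config$seed` and runs [simulate_genotypes()],
#' [simulate_modifications()] and [simulate_expression()], then assembles the
#' SNP-to-gene assignment: planted SNPs map to the gene they drive, all
#' other SNPs are spread across genes in order (`snp i -> gene ((i-1) mod
#' n_genes) + 1`), emulating host-gene assignment.
#'
#' @param config A [simulation_config()].
#' @return A `paired_cohort`: list with matrices `genotypes_normal`,
#'   `genotypes_tumor` (SNP x patient), `cn_diff`, `beta_diff`,
#'   `expr_tumor`, `expr_normal` (gene x patient), `snp_gene_map`
#'   (data frame `snp_id`, `gene_id`), `maf`, `truth` and `config`.
#' @examples
#' cfg <- simulation_config(n_patients = 8, n_genes = 5, n_snps = 10, seed = 7)
#' ch <- simulate_cohort(cfg)
#' dim(ch$cn_diff)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  g <- simulate_genotypes(config)
  mod <- simulate_modifications(config, g$genotypes_normal)
  ex <- simulate_expression(config, mod$cn_diff, mod$beta_diff)

  gene_idx <- ((seq_len(config$n_snps) - 1L) %% config$n_genes) + 1L
  for (eff in list(config$planted_cnv_effects, config$planted_meth_effects)) {
    if (!is.null(eff)) gene_idx[eff$snp] <- eff$gene
  }
  snp_gene_map <- data.frame(snp_id = rownames(g$genotypes_normal),
                             gene_id = gene_ids(config$n_genes)[gene_idx],
                             stringsAsFactors = FALSE)
  truth <- mod$truth
  if (!is.null(truth$planted_cnv)) {
    truth$planted_cnv$snp_id <- rownames(g$genotypes_normal)[truth$planted_cnv$snp]
    truth$planted_cnv$gene_id <- rownames(mod$cn_diff)[truth$planted_cnv$gene]
  }
  if (!is.null(truth$planted_meth)) {
    truth$planted_meth$snp_id <- rownames(g$genotypes_normal)[truth$planted_meth$snp]
    truth$planted_meth$gene_id <- rownames(mod$cn_diff)[truth$planted_meth$gene]
  }
  truth$planted_de <- config$planted_de_effects
  if (!is.null(truth$planted_de)) {
    truth$planted_de$gene_id <- rownames(mod$cn_diff)[truth$planted_de$gene]
  }

  structure(list(
    genotypes_normal = g$genotypes_normal,
    genotypes_tumor = g$genotypes_tumor,
    maf = g$maf,
    cn_diff = mod$cn_diff,
    beta_diff = mod$beta_diff,
    expr_tumor = ex$expr_tumor,
    expr_normal = ex$expr_normal,
    snp_gene_map = snp_gene_map,
    truth = truth,
    config = config
  ), class = "paired_cohort")
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat(sprintf("paired_cohort: %d patients, %d genes, %d SNPs (seed %d)\n",
              x$config$n_patients, x$config$n_genes, x$config$n_snps,
              x$config$seed))
  n_cnv <- if (is.null(x$truth$planted_cnv)) 0L else nrow(x$truth$planted_cnv)
  n_met <- if (is.null(x$truth$planted_meth)) 0L else nrow(x$truth$planted_meth)
  n_de <- if (is.null(x$truth$planted_de)) 0L else nrow(x$truth$planted_de)
  cat(sprintf("planted effects: %d CNV, %d methylation, %d DE\n",
              n_cnv, n_met, n_de))
  invisible(x)
}
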