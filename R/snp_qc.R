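# SNP quality control: minor allele frequency, exact Hardy-Weinberg test,
# Bowker's symmetry test on paired tumor/normal genotypes.
# Genotypes are minor-allele counts (0/1/2, NA = missing) and QC is
# computed from germline (normal-tissue) calls.

#' Minor allele frequency of one genotype row
#'
#' Counts alleles over the `2n` chromosomes of the non-missing calls and
#' returns the frequency of the rarer allele, regardless of which allele the
#' 0/1/2 coding treats as "minor".
#'
#' @param genotype_row Integer vector of 0/1/2 calls, NA = missing.
#' @return MAF in `[0, 0.5]`.
#' @export
minor_allele_frequency <- function(genotype_row) {
  g <- genotype_row[!is.na(genotype_row)]
  if (length(g) == 0L) stop("all genotypes missing")
  if (any(!g %in% 0:2)) stop("genotypes must be coded 0/1/2")
  f <- sum(g) / (2 * length(g))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed minor-allele count, all
#' compatible heterozygote counts are enumerated and the probabilities of
#' configurations no more likely than the observed one (within a `1e-7`
#' relative tie tolerance) are summed under the HWE conditional
#' distribution. Appropriate at small cohort sizes where the chi-square
#' approximation breaks down.
#'
#' @param n_hom_major,n_het,n_hom_minor Genotype counts (non-negative,
#'   total >= 1).
#' @return Exact p-value in `(0, 1]`. Monomorphic input (a single attainable
#'   configuration) gives 1.
#' @export
hwe_exact_test <- function(n_hom_major, n_het, n_hom_minor) {
  counts <- c(n_hom_major, n_het, n_hom_minor)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n < 1L) stop("total count must be >= 1")
  n_a <- 2 * n_hom_minor + n_het            # alleles of the coded-minor type
  m <- min(n_a, 2 * n - n_a)                # rarer-allele count (label-free)
  if (m == 0L) return(1)
  hets <- seq(m %% 2, min(m, 2 * n - m), by = 2)
  # log P(het = h | m, n) up to a constant: 2^h / (hom_rare! h! hom_common!)
  hom_rare <- (m - hets) / 2
  hom_common <- n - hets - hom_rare
  logw <- hets * log(2) - lgamma(hom_rare + 1) - lgamma(hets + 1) -
    lgamma(hom_common + 1)
  prob <- exp(logw - max(logw))
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_het, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

#' Bowker's test of symmetry for paired genotype calls
#'
#' Tests whether tumor-vs-normal genotype changes are symmetric: the
#' chi-square statistic sums `(n_ij - n_ji)^2 / (n_ij + n_ji)` over
#' off-diagonal pairs. By default degrees of freedom count only informative
#' pairs (`n_ij + n_ji > 0`); the textbook fixed `k(k-1)/2` is available via
#' `df_fixed = TRUE` (statistic unchanged, uninformative pairs contribute 0).
#' An all-diagonal table (no discordant pair) gives chi-square 0, p = 1.
#'
#' @param tab Square contingency table of counts, rows = normal genotype,
#'   columns = tumor genotype (patients with both calls non-missing).
#' @param df_fixed Use fixed `k(k-1)/2` degrees of freedom.
#' @return List: `chi2`, `df`, `p_value`.
#' @export
bowker_test <- function(tab, df_fixed = FALSE) {
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) stop("table must be square")
  if (any(tab < 0)) stop("counts must be non-negative")
  k <- nrow(tab)
  chi2 <- 0
  df <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      tot <- tab[i, j] + tab[j, i]
      if (tot > 0) {
        chi2 <- chi2 + (tab[i, j] - tab[j, i])^2 / tot
        df <- df + 1L
      }
    }
  }
  if (df_fixed) df <- as.integer(k * (k - 1L) / 2)
  p <- if (df == 0L) 1 else pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p_value = p)
}

#' Cross-tabulate paired genotype calls
#'
#' @param normal_row,tumor_row Genotype vectors (0/1/2/NA) for the same
#'   patients; pairs with any missing call are dropped.
#' @return 3x3 count matrix, rows = normal, columns = tumor.
#' @export
paired_genotype_table <- function(normal_row, tumor_row) {
  stopifnot(length(normal_row) == length(tumor_row))
  ok <- !is.na(normal_row) & !is.na(tumor_row)
  tab <- table(factor(normal_row[ok], levels = 0:2),
               factor(tumor_row[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 3L, 3L,
              dimnames = list(normal = 0:2, tumor = 0:2))
  m
}

#' Filter SNPs by minor allele frequency and Hardy-Weinberg equilibrium
#'
#' Retains SNPs with `maf >= maf_min` and exact-HWE p-value strictly above
#' `hwe_p_min`, computed from germline (normal-tissue) genotypes. When tumor
#' genotypes are supplied, Bowker's symmetry test of tumor-vs-normal calls
#' is added to the QC table (it does not affect retention; it audits whether
#' somatic genotype discordance is negligible).
#'
#' @param genotypes_normal SNP x patient matrix of 0/1/2/NA calls.
#' @param maf_min MAF threshold (default 0.01).
#' @param hwe_p_min HWE p-value threshold; SNPs with p-value <=
#'   `hwe_p_min` are excluded (default 0.05).
#' @param genotypes_tumor Optional matching tumor genotype matrix.
#' @return List: `retained` (character vector of SNP ids) and `qc` (data
#'   frame with `snp_id`, `maf`, `hwe_p`, `passes`, and `bowker_chi2`,
#'   `bowker_df`, `bowker_p` when tumor genotypes were given).
#' @export
filter_snps <- function(genotypes_normal, maf_min = 0.01, hwe_p_min = 0.05,
                        genotypes_tumor = NULL) {
  stopifnot(is.matrix(genotypes_normal))
  ids <- rownames(genotypes_normal)
  if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(nrow(genotypes_normal)))
  n_snp <- nrow(genotypes_normal)
  maf <- numeric(n_snp)
  hwe_p <- numeric(n_snp)
  for (i in seq_len(n_snp)) {
    g <- genotypes_normal[i, ]
    g <- g[!is.na(g)]
    if (length(g) == 0L) {
      maf[i] <- NA_real_
      hwe_p[i] <- NA_real_
      next
    }
    counts <- tabulate(g + 1L, nbins = 3L)
    f <- (2 * counts[3L] + counts[2L]) / (2 * sum(counts))
    maf[i] <- min(f, 1 - f)
    hwe_p[i] <- hwe_exact_test(counts[1L], counts[2L], counts[3L])
  }
  passes <- !is.na(maf) & maf >= maf_min & !is.na(hwe_p) & hwe_p > hwe_p_min
  qc <- data.frame(snp_id = ids, maf = maf, hwe_p = hwe_p, passes = passes,
                   stringsAsFactors = FALSE)
  if (!is.null(genotypes_tumor)) {
    stopifnot(identical(dim(genotypes_tumor), dim(genotypes_normal)))
    bw <- t(vapply(seq_len(n_snp), function(i) {
      b <- bowker_test(paired_genotype_table(genotypes_normal[i, ],
                                             genotypes_tumor[i, ]))
      c(b$chi2, b$df, b$p_value)
    }, numeric(3L)))
    qc$bowker_chi2 <- bw[, 1L]
    qc$bowker_df <- as.integer(bw[, 2L])
    qc$bowker_p <- bw[, 3L]
  }
  list(retained = ids[passes], qc = qc)
}
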