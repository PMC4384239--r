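# Expression linkage: do cascade-surviving SNP groupings show differential
# tumor/normal expression change, and is its direction concordant with the
# modification direction?

#' Rank test of expression log-ratios across genotype-code groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test (exact when sample sizes
#' permit and there are no ties, per [stats::wilcox.test()] defaults).
#' Three or more groups: tie-corrected Kruskal-Wallis, which reduces to the
#' rank-sum test at two groups.
#'
#' @param log_ratios Per-patient expression log-ratios (tumor - normal).
#' @param codes Integer genotype codes per patient (NA dropped pairwise).
#' @return List: `statistic`, `p_value`, `method` (`"wilcoxon"` or
#'   `"kruskal-wallis"`), `k` (number of non-empty groups).
#' @export
expression_group_test <- function(log_ratios, codes) {
  stopifnot(length(log_ratios) == length(codes))
  ok <- !is.na(log_ratios) & !is.na(codes)
  groups <- split(log_ratios[ok], codes[ok])
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  if (k == 2L) {
    if (length(unique(unlist(groups))) == 1L) {
      return(list(statistic = NA_real_, p_value = 1, method = "wilcoxon",
                  k = 2L))
    }
    wt <- suppressWarnings(wilcox.test(groups[[1L]], groups[[2L]]))
    return(list(statistic = unname(wt$statistic), p_value = wt$p.value,
                method = "wilcoxon", k = 2L))
  }
  kw <- kruskal_wallis(groups)
  list(statistic = kw$statistic, p_value = kw$p_value,
       method = "kruskal-wallis", k = k)
}

#' Classify concordance between modification and expression direction
#'
#' The expected expression sign of a modification is +1 for amplification
#' and hypomethylation (dosage gain / promoter de-repression raises
#' expression) and -1 for deletion and hypermethylation. The observed sign
#' is that of the carrier group's median log-ratio. Agreement is concordant
#' (`"+"`), disagreement discordant (`"-"`); a zero median is
#' `"undetermined"`.
#'
#' @param direction One of `"amplification"`, `"deletion"`,
#'   `"hypermethylation"`, `"hypomethylation"`.
#' @param median_log_ratio Median expression log-ratio of the carrier group.
#' @return `"+"`, `"-"` or `"undetermined"`.
#' @export
classify_concordance <- function(direction, median_log_ratio) {
  expected <- switch(direction,
                     amplification = 1,
                     hypomethylation = 1,
                     deletion = -1,
                     hypermethylation = -1,
                     stop("unknown direction: ", direction))
  if (is.na(median_log_ratio) || median_log_ratio == 0) return("undetermined")
  if (sign(median_log_ratio) == expected) "+" else "-"
}

#' Link cascade survivors to expression changes
#'
#' For every SNP-gene-layer-direction combination that survived all three
#' cascade stages, tests the per-patient expression log-ratios (tumor minus
#' normal) across the genotype-code groups and classifies concordance from
#' the carrier-group median. When both coding models survived, the
#' qualitative grouping is used for the test (simpler groups) and both
#' surviving models are recorded.
#'
#' @param records A `cascade_records` data frame from [run_cascade()].
#' @param cohort The `paired_cohort` the records were computed on.
#' @param expr_threshold Significance threshold on the rank-test p-value
#'   (default 0.05); concordance is classified only for significant links,
#'   otherwise `"undetermined"`.
#' @param tested_allele Allele used for coding (must match the cascade).
#' @return A `link_records` data frame, one row per surviving
#'   SNP-gene-layer-direction: `expr_stat`, `expr_p`,
#'   `median_log_ratio_carriers`, `linked` (p below threshold),
#'   `concordance`, `models_passed`.
#' @export
link_expression <- function(records, cohort, expr_threshold = 0.05,
                            tested_allele = "minor") {
  surv <- records[records$stage_passed == "kw", , drop = FALSE]
  out <- list()
  if (nrow(surv) > 0L) {
    key <- paste(surv$snp_id, surv$gene_id, surv$layer, surv$direction,
                 sep = "\r")
    for (u in unique(key)) {
      rows <- surv[key == u, , drop = FALSE]
      model <- if ("qualitative" %in% rows$model) "qualitative"
               else rows$model[1L]
      snp <- rows$snp_id[1L]
      gene <- rows$gene_id[1L]
      cg <- code_genotypes(cohort$genotypes_normal[snp, ], model,
                           tested_allele)
      lr <- cohort$expr_tumor[gene, ] - cohort$expr_normal[gene, ]
      ts <- expression_group_test(lr, cg$codes)
      carriers <- !is.na(cg$codes) & cg$codes >= 1L
      med <- if (any(carriers)) median(lr[carriers]) else NA_real_
      linked <- !is.na(ts$p_value) && ts$p_value < expr_threshold
      conc <- if (linked) {
        classify_concordance(rows$direction[1L], med)
      } else "undetermined"
      out[[length(out) + 1L]] <- data.frame(
        snp_id = snp, gene_id = gene, layer = rows$layer[1L],
        direction = rows$direction[1L], model = model,
        models_passed = paste(sort(unique(rows$model)), collapse = ";"),
        expr_stat = ts$statistic, expr_p = ts$p_value,
        median_log_ratio_carriers = med, linked = linked,
        concordance = conc, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(snp_id = character(0), gene_id = character(0),
               layer = character(0), direction = character(0),
               model = character(0), models_passed = character(0),
               expr_stat = numeric(0), expr_p = numeric(0),
               median_log_ratio_carriers = numeric(0), linked = logical(0),
               concordance = character(0), stringsAsFactors = FALSE)
  }
  attr(res, "expr_threshold") <- expr_threshold
  class(res) <- c("link_records", "data.frame")
  res
}
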