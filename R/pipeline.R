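# End-to-end orchestration: differential expression -> modification calls
# -> SNP QC -> association cascade -> expression linkage, with stage-count
# logging and summary tables.

#' Pipeline configuration
#'
#' Collects every stage threshold with validation. The defaults are the
#' published operating points of the procedure this pipeline implements:
#' DE at p < 1e-9, copy-number calls at |CN_dif| >= 0.3, methylation calls
#' at |beta difference| >= 0.25, SNP QC at MAF >= 0.01 and HWE p > 0.05,
#' cascade stages at p < 0.01 each, expression linkage at p < 0.05.
#'
#' @param de_p Paired-t selection threshold.
#' @param cn_threshold,beta_threshold Modification-call magnitudes.
#' @param maf_min,hwe_p_min SNP QC thresholds.
#' @param t1,t2,t3 Fisher, regression and Kruskal-Wallis stage thresholds.
#' @param expr_p Expression-linkage rank-test threshold.
#' @param models Coding models to test.
#' @param tested_allele Allele whose carrier status is coded.
#' @param normalize Quantile-normalize expression before the paired t-tests.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(de_p = 1e-9, cn_threshold = 0.3,
                            beta_threshold = 0.25, maf_min = 0.01,
                            hwe_p_min = 0.05, t1 = 0.01, t2 = 0.01,
                            t3 = 0.01, expr_p = 0.05,
                            models = c("qualitative", "quantitative"),
                            tested_allele = "minor", normalize = TRUE) {
  for (p in c(de_p, hwe_p_min, t1, t2, t3, expr_p)) {
    if (!is.finite(p) || p <= 0 || p > 1) stop("p-value thresholds must be in (0, 1]")
  }
  if (cn_threshold <= 0 || beta_threshold <= 0 || beta_threshold > 2)
    stop("call thresholds out of range")
  if (maf_min < 0 || maf_min > 0.5) stop("maf_min must be in [0, 0.5]")
  models <- match.arg(models, c("qualitative", "quantitative"),
                      several.ok = TRUE)
  structure(list(de_p = de_p, cn_threshold = cn_threshold,
                 beta_threshold = beta_threshold, maf_min = maf_min,
                 hwe_p_min = hwe_p_min, t1 = t1, t2 = t2, t3 = t3,
                 expr_p = expr_p, models = models,
                 tested_allele = tested_allele, normalize = normalize),
            class = "pipeline_config")
}

#' Run the full regulatory-SNP pipeline on a paired cohort
#'
#' Sequences all stages: (optionally quantile-normalized) paired-t
#' differential expression, copy-number and methylation status calls, SNP
#' QC (MAF, exact HWE, Bowker symmetry), the three-stage association
#' cascade, and expression linkage with concordance classification. Every
#' filter's before/after counts are logged. Deterministic given the cohort
#' and configuration (no randomness is consumed).
#'
#' @param cohort A `paired_cohort`, or `NULL` to read one from `input_dir`.
#' @param config A [pipeline_config()].
#' @param input_dir Cohort directory (see [read_cohort()]); used when
#'   `cohort` is `NULL`.
#' @param output_dir When given, all result tables are written there as TSV.
#' @return List: `de` (gene-wise results), `de_summary`, `calls`, `qc`,
#'   `records` (cascade), `links`, `table1` (per-direction stage counts),
#'   `table2` (linked SNPs with concordance), `log` (stage count audit),
#'   `config`.
#' @export
run_full_pipeline <- function(cohort = NULL, config = pipeline_config(),
                              input_dir = NULL, output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(cohort)) {
    if (is.null(input_dir)) stop("supply a cohort or an input_dir")
    cohort <- read_cohort(input_dir)
  }

  et <- cohort$expr_tumor
  en <- cohort$expr_normal
  if (config$normalize) {
    joint <- quantile_normalize(cbind(et, en))
    et <- joint[, seq_len(ncol(et)), drop = FALSE]
    en <- joint[, ncol(et) + seq_len(ncol(en)), drop = FALSE]
  }
  de <- de_paired_t(et, en, threshold = config$de_p)
  de_summary <- select_de_genes(de, threshold = config$de_p)

  calls <- call_modifications(cohort, config$cn_threshold,
                              config$beta_threshold)
  qc <- filter_snps(cohort$genotypes_normal, config$maf_min,
                    config$hwe_p_min, cohort$genotypes_tumor)
  records <- run_cascade(cohort, calls, qc, models = config$models,
                         thresholds = c(config$t1, config$t2, config$t3),
                         tested_allele = config$tested_allele)
  links <- link_expression(records, cohort, expr_threshold = config$expr_p,
                           tested_allele = config$tested_allele)
  tables <- write_summary(records, links)

  pair_key <- unique(paste(records$snp_id, records$layer, records$direction))
  log <- data.frame(
    stage = c("de_genes", "snp_qc", "fisher", "regression", "kw",
              "expression_linked", "concordant"),
    n_in = c(nrow(de), nrow(cohort$genotypes_normal), length(pair_key),
             sum(records$stage_passed != "none"),
             sum(records$stage_passed %in% c("regression", "kw")),
             sum(records$stage_passed == "kw"), sum(links$linked)),
    n_out = c(de_summary$n_selected, length(qc$retained),
              sum(records$stage_passed != "none"),
              sum(records$stage_passed %in% c("regression", "kw")),
              sum(records$stage_passed == "kw"), sum(links$linked),
              sum(links$linked & links$concordance == "+")),
    stringsAsFactors = FALSE
  )

  result <- list(de = de, de_summary = de_summary, calls = calls, qc = qc,
                 records = records, links = links, table1 = tables$table1,
                 table2 = tables$table2, log = log, config = config)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(output_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(de, "de_results.tsv")
    wt(qc$qc, "snp_qc.tsv")
    wt(as.data.frame(records), "cascade_records.tsv")
    wt(as.data.frame(links), "link_records.tsv")
    wt(tables$table1, "summary_stage_counts.tsv")
    wt(tables$table2, "summary_linked_snps.tsv")
    wt(log, "pipeline_log.tsv")
  }
  result
}

#' Summary tables of cascade and linkage results
#'
#' `table1`: one row per modification direction with unique-SNP counts at
#' each cascade stage plus expression-linked and concordant counts.
#' `table2`: one row per expression-linked SNP with its gene, layer,
#' direction and concordance sign. Column order is fixed.
#'
#' @param records A `cascade_records` data frame.
#' @param links A `link_records` data frame from [link_expression()].
#' @return List with data frames `table1` and `table2`.
#' @export
write_summary <- function(records, links) {
  t1 <- stage_summary(records)
  per_dir <- function(f) {
    vapply(seq_len(nrow(t1)), function(i) {
      sel <- links$layer == t1$layer[i] & links$direction == t1$direction[i]
      f(links[sel, , drop = FALSE])
    }, integer(1L))
  }
  t1$expression_linked <- per_dir(function(d) length(unique(d$snp_id[d$linked])))
  t1$concordant <- per_dir(function(d)
    length(unique(d$snp_id[d$linked & d$concordance == "+"])))
  t2 <- links[links$linked,
              c("layer", "direction", "gene_id", "snp_id", "concordance"),
              drop = FALSE]
  rownames(t2) <- NULL
  list(table1 = t1, table2 = as.data.frame(t2))
}
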