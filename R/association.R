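# The association cascade: genotype coding, carrier-by-status contingency
# tables, Fisher's exact test (2x2 and rx2 Freeman-Halton by full
# margin-preserving enumeration), OLS regression of modification magnitude
# on the genotype code, and a Kruskal-Wallis stage, each gated at its own
# p-value threshold.

#' Code a genotype row under the qualitative or quantitative model
#'
#' Qualitative (dominant) coding marks carriers of the tested allele with 1,
#' non-carriers 0; quantitative (additive) coding counts copies of the
#' tested allele (0/1/2). The tested allele defaults to the minor allele. A
#' row whose non-missing codes are all identical carries no contrast and is
#' flagged untestable.
#'
#' @param genotype_row Integer 0/1/2/NA vector (minor-allele counts).
#' @param model `"qualitative"` or `"quantitative"`.
#' @param tested_allele `"minor"` or `"major"`.
#' @return List: `codes` (integer, NA where the genotype is missing),
#'   `model`, `tested_allele`, `untestable`.
#' @export
code_genotypes <- function(genotype_row,
                           model = c("qualitative", "quantitative"),
                           tested_allele = c("minor", "major")) {
  model <- match.arg(model)
  tested_allele <- match.arg(tested_allele)
  if (any(!genotype_row[!is.na(genotype_row)] %in% 0:2))
    stop("genotypes must be coded 0/1/2")
  codes <- genotype_code(genotype_row, model, tested_allele)
  defined <- codes[!is.na(codes)]
  list(codes = codes, model = model, tested_allele = tested_allele,
       untestable = length(unique(defined)) < 2L)
}

#' Build a code-by-modification contingency table
#'
#' Rows are the genotype-code levels present among the complete patients (2
#' under the qualitative model, up to 3 under the quantitative model);
#' columns are (modified, unmodified) for one tested direction. Patients
#' with a missing code or missing status are excluded.
#'
#' @param codes Integer codes per patient (NA = missing).
#' @param modified Logical per patient: modified in the tested direction.
#' @return Integer matrix (r x 2) with code levels as row names and columns
#'   `modified`, `unmodified`.
#' @export
build_contingency <- function(codes, modified) {
  stopifnot(length(codes) == length(modified))
  ok <- !is.na(codes) & !is.na(modified)
  if (!any(ok)) stop("no patient has both code and status defined")
  codes <- codes[ok]
  modified <- as.logical(modified[ok])
  lev <- sort(unique(codes))
  tab <- vapply(lev, function(l) {
    c(sum(codes == l & modified), sum(codes == l & !modified))
  }, integer(2L))
  matrix(t(tab), nrow = length(lev), ncol = 2L,
         dimnames = list(code = lev, status = c("modified", "unmodified")))
}

#' Two-sided Fisher's exact test for 2x2 and rx2 tables
#'
#' Full enumeration over all tables with the observed margins: the two-sided
#' p-value is the total probability of tables whose (multivariate)
#' hypergeometric probability does not exceed that of the observed table,
#' with a `1e-7` relative tolerance for ties. For a 2x2 table this is the
#' classical Fisher test; for a 3x2 table it is the Freeman-Halton
#' extension. A table with a zero row or column margin admits a single
#' configuration and returns 1.
#'
#' @param tab Non-negative integer matrix, 2 columns, at most 3 rows.
#' @return Two-sided exact p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers")
  if (ncol(tab) != 2L) stop("table must have 2 columns")
  r <- nrow(tab)
  if (r < 1L || r > 3L) stop("table must have 1-3 rows")
  R <- rowSums(tab)
  C1 <- sum(tab[, 1L])
  N <- sum(tab)
  if (N == 0L || r == 1L || C1 == 0L || C1 == N) return(1)

  if (r == 2L) {
    x1 <- max(0L, C1 - R[2L]):min(R[1L], C1)
    logp <- lchoose(R[1L], x1) + lchoose(R[2L], C1 - x1) - lchoose(N, C1)
    obs <- tab[1L, 1L]
    log_obs <- lchoose(R[1L], obs) + lchoose(R[2L], C1 - obs) - lchoose(N, C1)
  } else {
    x1v <- integer(0)
    x2v <- integer(0)
    for (a in 0:min(R[1L], C1)) {
      lo <- max(0L, C1 - a - R[3L])
      hi <- min(R[2L], C1 - a)
      if (lo > hi) next
      b <- lo:hi
      x1v <- c(x1v, rep.int(a, length(b)))
      x2v <- c(x2v, b)
    }
    logp <- lchoose(R[1L], x1v) + lchoose(R[2L], x2v) +
      lchoose(R[3L], C1 - x1v - x2v) - lchoose(N, C1)
    log_obs <- lchoose(R[1L], tab[1L, 1L]) + lchoose(R[2L], tab[2L, 1L]) +
      lchoose(R[3L], tab[3L, 1L]) - lchoose(N, C1)
  }
  prob <- exp(logp)
  p_obs <- exp(log_obs)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

#' Regression stage: does the genotype code predict modification magnitude?
#'
#' Ordinary least squares of the per-patient modification magnitude
#' (CN difference or beta difference) on the genotype code, with a two-sided
#' t-test on the slope (`n - 2` degrees of freedom). Degenerate cases are
#' flagged rather than dropped: a constant response gives slope 0, p = 1
#' (`flag = "constant_response"`); a perfect fit (zero residual variance
#' with a non-zero slope) gives p = 0 with a warning
#' (`flag = "perfect_fit"`).
#'
#' @param codes Integer codes per patient (NA = missing).
#' @param magnitudes Numeric modification magnitudes per patient.
#' @return List: `slope` (magnitude units per code unit), `p_value`, `n`,
#'   `flag` (`"ok"` or a degenerate-case label).
#' @export
regression_stage <- function(codes, magnitudes) {
  stopifnot(length(codes) == length(magnitudes))
  ok <- !is.na(codes) & !is.na(magnitudes)
  x <- as.numeric(codes[ok])
  y <- as.numeric(magnitudes[ok])
  n <- length(x)
  if (n < 3L) stop("need at least 3 patients with code and magnitude")
  if (var(x) == 0) stop("constant genotype code: untestable")
  if (var(y) == 0) {
    return(list(slope = 0, p_value = 1, n = n, flag = "constant_response"))
  }
  fit <- lm(y ~ x)
  # summary() itself warns on a perfect fit; we flag that case explicitly
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- co["x", "Estimate"]
  if (sm$sigma^2 <= .Machine$double.eps * var(y)) {
    warning("zero residual variance: slope fits perfectly, p reported as 0")
    return(list(slope = slope, p_value = 0, n = n, flag = "perfect_fit"))
  }
  list(slope = slope, p_value = co["x", "Pr(>|t|)"], n = n, flag = "ok")
}

#' Kruskal-Wallis test over genotype-code groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on `k - 1`
#' degrees of freedom (via [stats::kruskal.test()]). With two groups this is
#' equivalent to the two-sided normal-approximation Wilcoxon rank-sum test
#' without continuity correction. All observations identical (complete ties)
#' gives H = 0, p = 1.
#'
#' @param groups List of numeric vectors (one per code level); empty groups
#'   are dropped.
#' @return List: `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups <- groups[lengths(groups) > 0L]
  k <- length(groups)
  if (k < 2L) stop("need at least 2 non-empty groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L) {
    return(list(statistic = 0, p_value = 1, df = k - 1L))
  }
  g <- factor(rep.int(seq_len(k), lengths(groups)))
  kt <- kruskal.test(values, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

cascade_directions <- list(
  cnv = c("amplification", "deletion"),
  methylation = c("hypermethylation", "hypomethylation")
)

direction_modified <- function(status_row, direction) {
  target <- switch(direction,
                   amplification = "amplified",
                   deletion = "deleted",
                   hypermethylation = "hyper",
                   hypomethylation = "hypo",
                   stop("unknown direction: ", direction))
  ifelse(is.na(status_row), NA, status_row == target)
}

#' Run the three-stage association cascade
#'
#' For each QC-passing SNP paired with its host gene, each modification
#' layer (`cnv`, `methylation`), each direction (amplification/deletion or
#' hyper-/hypomethylation) and each coding model: Fisher's exact test on the
#' code-by-status table, then -- for survivors -- OLS regression of the
#' modification magnitude on the code, then a Kruskal-Wallis test across
#' code groups, each gated at its threshold (all default 0.01). Stage
#' statistics are only computed (and reported) once the previous stage has
#' passed. Pairs whose status vector lacks both a modified and an unmodified
#' patient, and codings without contrast, are skipped and logged.
#'
#' @param cohort A `paired_cohort` (or equivalent list of matrices plus
#'   `snp_gene_map`).
#' @param calls Modification calls from [call_modifications()]; computed
#'   from the cohort when `NULL`.
#' @param qc QC result from [filter_snps()]; computed when `NULL`.
#' @param models Coding models to test (default both).
#' @param thresholds Length-3 numeric: Fisher, regression and Kruskal-Wallis
#'   stage p-value thresholds (default 0.01 each).
#' @param layers Modification layers to test (default both).
#' @param tested_allele Allele whose carrier status is coded (default
#'   `"minor"`).
#' @return A `cascade_records` data frame: one row per tested
#'   SNP-gene-layer-direction-model combination with `fisher_p`,
#'   `regression_slope`, `regression_p`, `kw_stat`, `kw_p`, `stage_passed`
#'   (`none`/`fisher`/`regression`/`kw`) and the flattened contingency
#'   table in `n_per_cell`. Attributes: `thresholds`, `skipped` (log of
#'   skipped pairs with reasons).
#' @export
run_cascade <- function(cohort, calls = NULL, qc = NULL,
                        models = c("qualitative", "quantitative"),
                        thresholds = c(0.01, 0.01, 0.01),
                        layers = c("cnv", "methylation"),
                        tested_allele = "minor") {
  stopifnot(length(thresholds) == 3L, all(thresholds > 0 & thresholds <= 1))
  models <- match.arg(models, c("qualitative", "quantitative"),
                      several.ok = TRUE)
  layers <- match.arg(layers, c("cnv", "methylation"), several.ok = TRUE)
  if (is.null(calls)) calls <- call_modifications(cohort)
  if (is.null(qc)) {
    qc <- filter_snps(cohort$genotypes_normal,
                      genotypes_tumor = cohort$genotypes_tumor)
  }
  snps <- intersect(qc$retained, cohort$snp_gene_map$snp_id)
  gene_of <- setNames(cohort$snp_gene_map$gene_id, cohort$snp_gene_map$snp_id)

  status_mat <- list(cnv = calls$cnv_status, methylation = calls$meth_status)
  magn_mat <- list(cnv = cohort$cn_diff, methylation = cohort$beta_diff)

  # Fisher p memoized by table cells: tables recur heavily across SNPs.
  memo <- new.env(hash = TRUE, parent = emptyenv())
  fisher_memo <- function(tab) {
    key <- paste(c(nrow(tab), tab), collapse = ",")
    v <- memo[[key]]
    if (is.null(v)) {
      v <- fisher_exact(tab)
      memo[[key]] <- v
    }
    v
  }

  cap <- length(snps) * length(layers) * 2L * length(models)
  rec <- list(snp_id = character(cap), gene_id = character(cap),
              layer = character(cap), direction = character(cap),
              model = character(cap), fisher_p = rep(NA_real_, cap),
              regression_slope = rep(NA_real_, cap),
              regression_p = rep(NA_real_, cap),
              kw_stat = rep(NA_real_, cap), kw_p = rep(NA_real_, cap),
              stage_passed = character(cap), n_per_cell = character(cap))
  k <- 0L
  skipped <- list()
  note_skip <- function(snp, gene, layer, direction, model, reason) {
    skipped[[length(skipped) + 1L]] <<-
      data.frame(snp_id = snp, gene_id = gene, layer = layer,
                 direction = direction, model = model, reason = reason,
                 stringsAsFactors = FALSE)
  }

  codings <- list()
  for (snp in snps) {
    gene <- gene_of[[snp]]
    if (is.null(gene) || !(gene %in% rownames(magn_mat[[layers[1L]]]))) {
      note_skip(snp, NA_character_, NA_character_, NA_character_,
                NA_character_, "gene_not_in_cohort")
      next
    }
    grow <- cohort$genotypes_normal[snp, ]
    codings <- lapply(setNames(models, models), function(mod) {
      code_genotypes(grow, mod, tested_allele)
    })
    for (layer in layers) {
      status_row <- status_mat[[layer]][gene, ]
      magn_row <- magn_mat[[layer]][gene, ]
      for (direction in cascade_directions[[layer]]) {
        modified <- direction_modified(status_row, direction)
        md <- modified[!is.na(modified)]
        if (!any(md) || all(md)) {
          note_skip(snp, gene, layer, direction, NA_character_,
                    "no_status_contrast")
          next
        }
        for (model in models) {
          cg <- codings[[model]]
          if (cg$untestable) {
            note_skip(snp, gene, layer, direction, model, "untestable_code")
            next
          }
          tab <- build_contingency(cg$codes, modified)
          fp <- fisher_memo(tab)
          k <- k + 1L
          rec$snp_id[k] <- snp
          rec$gene_id[k] <- gene
          rec$layer[k] <- layer
          rec$direction[k] <- direction
          rec$model[k] <- model
          rec$fisher_p[k] <- fp
          rec$n_per_cell[k] <- paste(apply(tab, 1L, paste, collapse = ","),
                                     collapse = ";")
          stage <- "none"
          if (fp < thresholds[1L]) {
            stage <- "fisher"
            rg <- regression_stage(cg$codes, magn_row)
            rec$regression_slope[k] <- rg$slope
            rec$regression_p[k] <- rg$p_value
            if (rg$p_value < thresholds[2L]) {
              stage <- "regression"
              groups <- split(magn_row[!is.na(cg$codes)],
                              cg$codes[!is.na(cg$codes)])
              kw <- kruskal_wallis(groups)
              rec$kw_stat[k] <- kw$statistic
              rec$kw_p[k] <- kw$p_value
              if (kw$p_value < thresholds[3L]) stage <- "kw"
            }
          }
          rec$stage_passed[k] <- stage
        }
      }
    }
  }
  records <- data.frame(lapply(rec, function(v) v[seq_len(k)]),
                        stringsAsFactors = FALSE)
  attr(records, "thresholds") <- thresholds
  attr(records, "skipped") <- if (length(skipped)) {
    do.call(rbind, skipped)
  } else {
    data.frame(snp_id = character(0), gene_id = character(0),
               layer = character(0), direction = character(0),
               model = character(0), reason = character(0))
  }
  class(records) <- c("cascade_records", "data.frame")
  records
}

#' Per-direction survivor counts across the cascade stages
#'
#' Counts unique SNPs passing each stage per modification direction; a SNP
#' counts once per direction if it passes under either coding model, so the
#' counts are monotone non-increasing along the stage order.
#'
#' @param records A `cascade_records` data frame from [run_cascade()].
#' @return Data frame: `layer`, `direction`, `fisher`, `regression`, `kw`.
#' @export
stage_summary <- function(records) {
  dirs <- data.frame(
    layer = rep(names(cascade_directions), lengths(cascade_directions)),
    direction = unlist(cascade_directions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  count_stage <- function(layer, direction, stages) {
    sel <- records$layer == layer & records$direction == direction &
      records$stage_passed %in% stages
    length(unique(records$snp_id[sel]))
  }
  dirs$fisher <- mapply(count_stage, dirs$layer, dirs$direction,
                        MoreArgs = list(stages = c("fisher", "regression", "kw")))
  dirs$regression <- mapply(count_stage, dirs$layer, dirs$direction,
                            MoreArgs = list(stages = c("regression", "kw")))
  dirs$kw <- mapply(count_stage, dirs$layer, dirs$direction,
                    MoreArgs = list(stages = "kw"))
  dirs
}
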