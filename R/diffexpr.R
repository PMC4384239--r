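# Differential expression for the paired design: quantile normalization,
# per-gene paired t-tests, Bonferroni reference threshold, DE selection.

#' Quantile-normalize an expression matrix
#'
#' Forces every column (array) to share the same value distribution: the
#' per-rank across-column means. Ties within a column receive the mean of
#' their rank-range values. Delegates to [limma::normalizeQuantiles()] with
#' tie averaging.
#'
#' @param x Numeric gene x sample matrix, no missing values.
#' @return Matrix of the same dimensions with identical column distributions.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 0L || ncol(x) < 1L) stop("empty matrix")
  if (anyNA(x)) stop("missing values are not supported; filter or impute first")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Paired t-test for one gene
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the per-patient differences
#' `d = tumor - normal`, with a two-sided p-value from the t distribution on
#' `n - 1` degrees of freedom. Pairs with any missing value are dropped.
#' Zero-variance differences give an undefined statistic: `t` and `p` are
#' returned as `NA` with `undefined = TRUE`, and such genes are never
#' selected downstream.
#'
#' @param tumor_row,normal_row Numeric vectors of equal length (one patient
#'   per position).
#' @return List: `t_stat`, `p_value`, `df`, `n` (complete pairs),
#'   `mean_diff`, `undefined`.
#' @export
paired_t_test <- function(tumor_row, normal_row) {
  stopifnot(length(tumor_row) == length(normal_row))
  ok <- !is.na(tumor_row) & !is.na(normal_row)
  d <- tumor_row[ok] - normal_row[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 complete pairs")
  s <- sd(d)
  if (s == 0) {
    return(list(t_stat = NA_real_, p_value = NA_real_, df = n - 1L,
                n = n, mean_diff = mean(d), undefined = TRUE))
  }
  t_stat <- mean(d) / (s / sqrt(n))
  list(t_stat = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 1L),
       df = n - 1L, n = n, mean_diff = mean(d), undefined = FALSE)
}

#' Gene-wise paired differential expression
#'
#' Row-wise paired t-tests of tumor against matched normal expression.
#' Columns must be patient-aligned across the two matrices. Genes whose
#' differences have zero variance are reported with `NA` statistics
#' (undefined), never silently dropped.
#'
#' @param expr_tumor,expr_normal Gene x patient matrices (same dimensions,
#'   same patient order), typically quantile-normalized log2 intensities.
#' @param threshold Two-sided p-value threshold for the `selected` flag
#'   (default `1e-9`).
#' @return Data frame: `gene_id`, `t_stat`, `p_value`, `mean_log_ratio`,
#'   `direction` (`"up"`/`"down"`, `NA` when the mean log-ratio is 0 or the
#'   test undefined), `selected`.
#' @export
de_paired_t <- function(expr_tumor, expr_normal, threshold = 1e-9) {
  stopifnot(identical(dim(expr_tumor), dim(expr_normal)))
  if (ncol(expr_tumor) < 2L) stop("need at least 2 patient pairs")
  d <- expr_tumor - expr_normal
  if (anyNA(d)) {
    res <- apply(d, 1L, function(di) {
      di <- di[!is.na(di)]
      if (length(di) < 2L) return(c(NA_real_, NA_real_, NA_real_))
      s <- sd(di)
      if (s == 0) return(c(NA_real_, NA_real_, mean(di)))
      t <- mean(di) / (s / sqrt(length(di)))
      c(t, 2 * pt(-abs(t), df = length(di) - 1L), mean(di))
    })
    t_stat <- res[1L, ]; p <- res[2L, ]; m <- res[3L, ]
  } else {
    n <- ncol(d)
    m <- rowMeans(d)
    s <- sqrt(rowSums((d - m)^2) / (n - 1L))
    t_stat <- ifelse(s == 0, NA_real_, m / (s / sqrt(n)))
    p <- 2 * pt(-abs(t_stat), df = n - 1L)
  }
  direction <- ifelse(is.na(t_stat) | m == 0, NA_character_,
                      ifelse(m > 0, "up", "down"))
  data.frame(
    gene_id = if (is.null(rownames(expr_tumor)))
      sprintf("row%d", seq_len(nrow(expr_tumor))) else rownames(expr_tumor),
    t_stat = t_stat,
    p_value = p,
    mean_log_ratio = m,
    direction = direction,
    selected = !is.na(p) & p < threshold,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Bonferroni per-test threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 54675)  # 9.14e-07 to 3 significant figures
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Select differentially expressed genes and summarize directions
#'
#' Genes with a defined p-value below `threshold` are selected and labeled by
#' the sign of their mean log-ratio. Percentages are `100 * count / total`,
#' rounded to the nearest integer, and `NA` when nothing is selected.
#'
#' @param results Data frame from [de_paired_t()].
#' @param threshold Selection p-value threshold (default `1e-9`).
#' @return List: `genes` (the selected rows), `n_selected`, `n_up`,
#'   `n_down`, `pct_up`, `pct_down`.
#' @export
select_de_genes <- function(results, threshold = 1e-9) {
  stopifnot(all(c("p_value", "mean_log_ratio") %in% names(results)))
  sel <- results[!is.na(results$p_value) & results$p_value < threshold, ,
                 drop = FALSE]
  n_up <- sum(sel$mean_log_ratio > 0)
  n_down <- sum(sel$mean_log_ratio < 0)
  n <- nrow(sel)
  list(genes = sel,
       n_selected = n,
       n_up = n_up,
       n_down = n_down,
       pct_up = if (n > 0) round(100 * n_up / n) else NA_real_,
       pct_down = if (n > 0) round(100 * n_down / n) else NA_real_)
}
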