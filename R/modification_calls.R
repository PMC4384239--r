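# Copy-number and methylation status calling. Gene-level CN differences can
# be derived from ordered marker-level data via a simplified recursive
# binary segmentation honoring minimum-marker, breakpoint-p and
# signal-to-noise criteria; statuses are then called at fixed thresholds.

#' Segmentation acceptance criteria
#'
#' @param min_markers Minimum consecutive markers on each side of an
#'   accepted breakpoint (default 100).
#' @param break_p Maximum Welch t-test p-value for an accepted breakpoint
#'   (default 0.001).
#' @param min_snr Minimum signal-to-noise ratio of an accepted breakpoint,
#'   operationalized as |mean difference| / pooled SD (default 0.3).
#' @param min_abs_cn_change Copy-number difference magnitude at which a
#'   segment (or gene) is called amplified/deleted (default 0.3).
#' @return A `segment_criteria` list.
#' @export
segment_criteria <- function(min_markers = 100L, break_p = 0.001,
                             min_snr = 0.3, min_abs_cn_change = 0.3) {
  if (min_markers < 2L) stop("min_markers must be >= 2")
  if (break_p <= 0 || min_snr <= 0 || min_abs_cn_change <= 0)
    stop("criteria bounds must be positive")
  structure(list(min_markers = as.integer(min_markers), break_p = break_p,
                 min_snr = min_snr, min_abs_cn_change = min_abs_cn_change),
            class = "segment_criteria")
}

# Welch t-test over every admissible split of x; returns the best candidate
# (smallest p, ties broken by larger |t|, then leftmost) or NULL.
best_split <- function(x, min_markers) {
  n <- length(x)
  if (n < 2L * min_markers) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  s <- min_markers:(n - min_markers)        # left block = 1..s
  nl <- s
  nr <- n - s
  ml <- cs[s] / nl
  mr <- (cs[n] - cs[s]) / nr
  vl <- pmax((cs2[s] - nl * ml^2) / (nl - 1L), 0)
  vr <- pmax((cs2[n] - cs2[s] - nr * mr^2) / (nr - 1L), 0)
  se2 <- vl / nl + vr / nr
  delta <- ml - mr
  t <- ifelse(se2 > 0, delta / sqrt(se2),
              ifelse(delta == 0, NaN, sign(delta) * Inf))
  df <- ifelse(se2 > 0,
               se2^2 / ((vl / nl)^2 / (nl - 1L) + (vr / nr)^2 / (nr - 1L)),
               NA_real_)
  p <- ifelse(is.nan(t), NA_real_,
              ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df)))
  pooled <- sqrt(((nl - 1L) * vl + (nr - 1L) * vr) / (n - 2L))
  snr <- ifelse(pooled > 0, abs(delta) / pooled,
                ifelse(delta == 0, 0, Inf))
  ok <- !is.na(p)
  if (!any(ok)) return(NULL)
  cand <- which(ok)
  best <- cand[order(p[cand], -abs(t[cand]), cand)][1L]
  list(split = s[best], p = p[best], snr = snr[best], t = t[best])
}

segment_recurse <- function(x, offset, crit) {
  b <- best_split(x, crit$min_markers)
  if (is.null(b) || b$p > crit$break_p || b$snr < crit$min_snr) {
    return(data.frame(first = offset + 1L, last = offset + length(x),
                      mean = mean(x), n_markers = length(x)))
  }
  rbind(segment_recurse(x[seq_len(b$split)], offset, crit),
        segment_recurse(x[(b$split + 1L):length(x)], offset + b$split, crit))
}

#' Segment an ordered copy-number difference profile
#'
#' Recursive binary splitting: at each step the candidate breakpoint with the
#' smallest two-sample Welch t-test p-value is accepted only if both flanks
#' hold at least `min_markers` markers, the p-value is at most `break_p`,
#' and the signal-to-noise ratio (|mean difference| / pooled SD) is at least
#' `min_snr`; otherwise the region stays one segment. This is a simplified
#' stand-in for the segmentation a commercial array suite performs; only the
#' published acceptance criteria are honored, not any particular vendor
#' statistic.
#'
#' @param marker_values Numeric vector of copy-number log-differences for
#'   one patient, ordered by genomic position within one chromosome.
#' @param criteria A [segment_criteria()].
#' @param positions Optional marker genomic positions (same order); used to
#'   report segment coordinates as 0-based half-open `[start, end)`
#'   intervals. Defaults to marker index.
#' @return Data frame: `first`, `last` (1-based marker indices, inclusive),
#'   `start`, `end` (0-based half-open coordinates), `mean`, `n_markers`.
#' @export
segment_cn <- function(marker_values, criteria = segment_criteria(),
                       positions = NULL) {
  stopifnot(inherits(criteria, "segment_criteria"))
  x <- as.numeric(marker_values)
  if (length(x) == 0L) stop("no markers")
  if (anyNA(x)) stop("missing marker values are not supported")
  if (length(x) < criteria$min_markers) {
    warning("fewer markers than min_markers; returning a single segment")
    seg <- data.frame(first = 1L, last = length(x), mean = mean(x),
                      n_markers = length(x))
  } else {
    seg <- segment_recurse(x, 0L, criteria)
  }
  if (is.null(positions)) positions <- seq_along(x) - 1L
  stopifnot(length(positions) == length(x), !is.unsorted(positions))
  seg$start <- positions[seg$first]
  seg$end <- positions[seg$last] + 1L
  rownames(seg) <- NULL
  seg[, c("first", "last", "start", "end", "mean", "n_markers")]
}

#' Gene-level copy-number differences from segments or markers
#'
#' With segments: each gene's value is the length-weighted mean of the
#' segment means overlapping its interval (weights = overlap widths). With
#' marker-level input: the plain mean of the markers falling inside the gene.
#' All intervals are 0-based half-open on the same coordinate system. Genes
#' with no overlap get `NA`.
#'
#' @param x Either a segment data frame (columns `start`, `end`, `mean`,
#'   optional `chrom`) as from [segment_cn()], or a marker data frame with
#'   columns `pos` (optional `chrom`) and `value`.
#' @param genes Data frame with columns `start`, `end`, `gene_id`, optional
#'   `chrom` (0-based half-open).
#' @return Named numeric vector of per-gene CN differences.
#' @export
gene_cn_difference <- function(x, genes) {
  stopifnot(is.data.frame(genes), all(c("start", "end", "gene_id") %in% names(genes)))
  by_marker <- "pos" %in% names(x)
  if (by_marker) {
    stopifnot("value" %in% names(x))
    q <- IRanges::IRanges(start = x$pos + 1L, width = 1L)
  } else {
    stopifnot(all(c("start", "end", "mean") %in% names(x)))
    q <- IRanges::IRanges(start = x$start + 1L, end = x$end)
  }
  gr <- IRanges::IRanges(start = genes$start + 1L, end = genes$end)
  same_chrom <- if ("chrom" %in% names(x) && "chrom" %in% names(genes)) {
    function(i, j) x$chrom[i] == genes$chrom[j]
  } else function(i, j) rep(TRUE, length(i))

  hits <- IRanges::findOverlaps(q, gr)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  keep <- same_chrom(qi, si)
  qi <- qi[keep]; si <- si[keep]

  out <- setNames(rep(NA_real_, nrow(genes)), genes$gene_id)
  if (length(qi) == 0L) return(out)
  if (by_marker) {
    val <- x$value[qi]
    agg <- tapply(val, si, mean)
  } else {
    w <- pmin(x$end[qi], genes$end[si]) - pmax(x$start[qi], genes$start[si])
    agg <- tapply(seq_along(qi), si, function(k) {
      sum(x$mean[qi[k]] * w[k]) / sum(w[k])
    })
  }
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Call copy-number status from a CN difference
#'
#' Trichotomous call at the published inclusive thresholds: amplified when
#' `CN_dif >= min_abs`, deleted when `CN_dif <= -min_abs`, otherwise
#' neutral. `NA` input stays `NA`.
#'
#' @param cn_dif Numeric vector/matrix of CN differences (tumor - normal).
#' @param min_abs Threshold magnitude (default 0.3).
#' @return Character vector/matrix: `"amplified"`, `"deleted"`, `"neutral"`.
#' @export
call_cnv_status <- function(cn_dif, min_abs = 0.3) {
  out <- ifelse(is.na(cn_dif), NA_character_,
                ifelse(cn_dif >= min_abs, "amplified",
                       ifelse(cn_dif <= -min_abs, "deleted", "neutral")))
  if (is.matrix(cn_dif)) dimnames(out) <- dimnames(cn_dif)
  out
}

#' Call methylation-alteration status from a beta difference
#'
#' Hypermethylated when `beta_dif >= min_abs`, hypomethylated when
#' `beta_dif <= -min_abs` (inclusive bounds), otherwise unchanged. Inputs
#' outside `[-1, 1]` are an error (beta differences cannot exceed the beta
#' range).
#'
#' @param beta_dif Numeric vector/matrix of beta differences in `[-1, 1]`.
#' @param min_abs Threshold magnitude (default 0.25).
#' @return Character vector/matrix: `"hyper"`, `"hypo"`, `"unchanged"`.
#' @export
call_methylation_status <- function(beta_dif, min_abs = 0.25) {
  if (any(abs(beta_dif) > 1, na.rm = TRUE))
    stop("beta differences must lie in [-1, 1]")
  out <- ifelse(is.na(beta_dif), NA_character_,
                ifelse(beta_dif >= min_abs, "hyper",
                       ifelse(beta_dif <= -min_abs, "hypo", "unchanged")))
  if (is.matrix(beta_dif)) dimnames(out) <- dimnames(beta_dif)
  out
}

#' Call both modification layers for a cohort
#'
#' @param cohort A `paired_cohort` (or any list with `cn_diff` and
#'   `beta_diff` gene x patient matrices).
#' @param cn_threshold,beta_threshold Call thresholds (defaults 0.3, 0.25).
#' @return List with character matrices `cnv_status` and `meth_status`.
#' @export
call_modifications <- function(cohort, cn_threshold = 0.3,
                               beta_threshold = 0.25) {
  list(cnv_status = call_cnv_status(cohort$cn_diff, cn_threshold),
       meth_status = call_methylation_status(cohort$beta_diff, beta_threshold))
}

#' Read gene intervals from a BED file
#'
#' BED4 (chrom, start, end, name); BED is natively 0-based half-open, which
#' is the convention used throughout this package.
#'
#' @param path Path to a BED file.
#' @return Data frame: `chrom`, `start`, `end`, `gene_id`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("expected BED4: chrom, start, end, gene_id")
  data.frame(chrom = as.character(bed[[1L]]), start = as.integer(bed[[2L]]),
             end = as.integer(bed[[3L]]), gene_id = as.character(bed[[4L]]),
             stringsAsFactors = FALSE)
}
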