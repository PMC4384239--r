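test_that("segmentation leaves unsplittable signals as one segment", {
  crit <- segment_criteria(min_markers = 10)
  # constant signal: zero variance everywhere, no valid split
  seg <- segment_cn(rep(0.2, 100), crit)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean, 0.2)
  expect_equal(seg$n_markers, 100)
  # fewer markers than min_markers: single segment with a warning
  expect_warning(short <- segment_cn(rnorm(5), crit), "min_markers")
  expect_equal(nrow(short), 1)
})

test_that("a planted breakpoint is localized where the exhaustive scan puts it", {
  set.seed(71)
  crit <- segment_criteria(min_markers = 100)
  x <- c(rnorm(150, 0, 0.1), rnorm(150, 1, 0.1))
  seg <- segment_cn(x, crit)
  expect_equal(nrow(seg), 2)
  expect_lte(abs(seg$last[1] - 150), 2)
  expect_equal(seg$last[1], oracle_best_breakpoint(x, 100))
  expect_lt(abs(seg$mean[1] - 0), 0.05)
  expect_lt(abs(seg$mean[2] - 1), 0.05)
})

test_that("events shorter than min_markers are never split out", {
  crit <- segment_criteria(min_markers = 100)
  for (seed in 1:20) {
    set.seed(seed)
    x <- c(rnorm(55, 0, 0.1), rnorm(90, 1, 0.1), rnorm(55, 0, 0.1))
    seg <- segment_cn(x, crit)
    expect_equal(nrow(seg), 1)
  }
})

test_that("breakpoint recovery is stable across seeds (property)", {
  crit <- segment_criteria(min_markers = 20)
  for (seed in 1:20) {
    set.seed(seed + 400)
    x <- c(rnorm(60, -0.5, 0.1), rnorm(80, 0.8, 0.1))
    seg <- segment_cn(x, crit)
    # a segment boundary always lands at the planted breakpoint
    expect_true(any(abs(seg$last[-nrow(seg)] - 60) <= 2))
  }
})

test_that("segment coordinates honor supplied positions as half-open intervals", {
  set.seed(72)
  pos <- sort(sample(0:10000, 300))
  x <- c(rnorm(150, 0, 0.1), rnorm(150, 1, 0.1))
  seg <- segment_cn(x, segment_criteria(min_markers = 100), positions = pos)
  expect_equal(seg$start[1], pos[1])
  expect_equal(seg$end[nrow(seg)], pos[300] + 1)
})

test_that("gene-level CN difference weights overlapping segments by length", {
  genes <- data.frame(start = c(10, 0, 5000), end = c(30, 200, 6000),
                      gene_id = c("inside", "spanning", "outside"))
  segs <- data.frame(start = c(0, 100), end = c(100, 200),
                     mean = c(0.2, 0.6))
  v <- gene_cn_difference(segs, genes)
  expect_equal(unname(v["inside"]), 0.2)
  expect_equal(unname(v["spanning"]), 0.4)  # equal-length overlap
  expect_true(is.na(v["outside"]))
  # unequal overlap: 3/4 in the first segment
  genes2 <- data.frame(start = 50, end = 150, gene_id = "g")
  segs2 <- data.frame(start = c(0, 125), end = c(125, 200),
                      mean = c(0.0, 0.8))
  expect_equal(unname(gene_cn_difference(segs2, genes2)["g"]), 0.2)
})

test_that("gene-level CN difference from markers is the plain mean", {
  markers <- data.frame(pos = c(5, 15, 25, 500), value = c(0.1, 0.3, 0.5, 9))
  genes <- data.frame(start = c(0, 600), end = c(30, 700),
                      gene_id = c("g1", "nohit"))
  v <- gene_cn_difference(markers, genes)
  expect_equal(unname(v["g1"]), 0.3)
  expect_true(is.na(v["nohit"]))
})

test_that("status calls use inclusive thresholds and propagate NA", {
  expect_equal(call_cnv_status(0.35), "amplified")
  expect_equal(call_cnv_status(0.3), "amplified")
  expect_equal(call_cnv_status(-0.30), "deleted")
  expect_equal(call_cnv_status(0.0), "neutral")
  expect_equal(call_cnv_status(c(0.29, -0.29)), c("neutral", "neutral"))
  expect_true(is.na(call_cnv_status(NA_real_)))

  expect_equal(call_methylation_status(0.25), "hyper")
  expect_equal(call_methylation_status(-0.30), "hypo")
  expect_equal(call_methylation_status(0.10), "unchanged")
  expect_error(call_methylation_status(1.2), "\\[-1, 1\\]")
})

test_that("status calling is monotone in the copy-number difference", {
  x <- seq(-1, 1, by = 0.01)
  st <- call_cnv_status(x)
  num <- c(deleted = -1, neutral = 0, amplified = 1)[st]
  expect_true(all(diff(num) >= 0))
})

test_that("cohort-level calls match elementwise calls", {
  ch <- make_planted_cohort(seed = 73)
  calls <- call_modifications(ch)
  expect_identical(dim(calls$cnv_status), dim(ch$cn_diff))
  i <- 7; j <- 3
  expect_equal(calls$cnv_status[i, j], call_cnv_status(ch$cn_diff[i, j]))
  expect_equal(calls$meth_status[i, j],
               call_methylation_status(ch$beta_diff[i, j]))
})

test_that("BED gene intervals round-trip through read_gene_bed", {
  bed <- file.path(tempdir(), "genes.bed")
  writeLines(c("chr1\t0\t100\tgeneA", "chr2\t50\t80\tgeneB"), bed)
  g <- read_gene_bed(bed)
  expect_equal(g$gene_id, c("geneA", "geneB"))
  expect_equal(g$start, c(0L, 50L))
  expect_equal(g$end, c(100L, 80L))
  expect_error(read_gene_bed(file.path(tempdir(), "absent.bed")), "not found")
})
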