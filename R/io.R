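# Plain-text I/O: TSV matrices (patients as columns), cohort directories,
# minimal VCF genotype export.

#' Write / read a matrix as TSV with an id column
#'
#' First column `id` holds row names; remaining columns are patients.
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_matrix_tsv
#' @param integer_mode Read values as integers (genotypes).
#' @return `read_matrix_tsv`: the matrix.
#' @export
read_matrix_tsv <- function(path, integer_mode = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV matrix in ", path,
                             " (expected header row + id column): ",
                             conditionMessage(e)))
  if (nrow(df) == 0L || ncol(df) < 2L || names(df)[1L] != "id")
    stop("malformed TSV matrix in ", path,
         ": expected columns (id, <patient ids...>) and at least one row")
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df$id
  if (integer_mode) storage.mode(m) <- "integer" else storage.mode(m) <- "double"
  m
}

cohort_files <- c("genotypes_normal", "genotypes_tumor", "cn_diff",
                  "beta_diff", "expr_tumor", "expr_normal")

#' Write a paired cohort to a directory of TSV files
#'
#' One TSV per data layer (patients as columns), `snp_gene_map.tsv`, truth
#' tables for planted effects, and the generator configuration as YAML.
#'
#' @param cohort A `paired_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in cohort_files) {
    write_matrix_tsv(cohort[[f]], file.path(dir, paste0(f, ".tsv")))
  }
  write.table(cohort$snp_gene_map, file.path(dir, "snp_gene_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (tr in c("planted_cnv", "planted_meth", "planted_de")) {
    if (!is.null(cohort$truth[[tr]])) {
      write.table(cohort$truth[[tr]], file.path(dir, paste0("truth_", tr, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(cohort$config)) {
    cfg <- unclass(cohort$config)
    cfg <- lapply(cfg, function(x) if (is.data.frame(x)) as.list(x) else x)
    yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

#' Read a paired cohort from a directory written by [write_cohort()]
#'
#' Fails fast with a descriptive error naming the offending file when a
#' layer is missing, empty or malformed.
#'
#' @param dir Cohort directory.
#' @return A `paired_cohort`.
#' @export
read_cohort <- function(dir) {
  out <- list()
  for (f in cohort_files) {
    path <- file.path(dir, paste0(f, ".tsv"))
    out[[f]] <- read_matrix_tsv(path, integer_mode = grepl("genotypes", f))
  }
  pids <- colnames(out$genotypes_normal)
  for (f in cohort_files) {
    if (!identical(colnames(out[[f]]), pids))
      stop("patient columns of ", f, ".tsv do not match genotypes_normal.tsv")
  }
  map_path <- file.path(dir, "snp_gene_map.tsv")
  if (!file.exists(map_path)) stop("file not found: ", map_path)
  map <- read.table(map_path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(map)))
    stop("malformed ", map_path, ": expected columns snp_id, gene_id")
  out$snp_gene_map <- map
  out$truth <- list()
  for (tr in c("planted_cnv", "planted_meth", "planted_de")) {
    p <- file.path(dir, paste0("truth_", tr, ".tsv"))
    if (file.exists(p)) {
      out$truth[[tr]] <- read.table(p, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    }
  }
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    cfg <- yaml::read_yaml(cfg_path)
    for (f in c("planted_cnv_effects", "planted_meth_effects",
                "planted_de_effects")) {
      if (!is.null(cfg[[f]])) cfg[[f]] <- as.data.frame(cfg[[f]])
    }
    out$config <- do.call(simulation_config, cfg)
  }
  structure(out, class = "paired_cohort")
}

#' Export genotypes as a minimal VCF (GT field only, unphased)
#'
#' Placeholder REF/ALT alleles (A/C): the pipeline operates on allele
#' counts, not sequence. Positions are the SNP row index on a single
#' synthetic contig unless supplied.
#'
#' @param genotypes SNP x patient 0/1/2/NA matrix.
#' @param path Output path.
#' @param chrom Contig name (default `"1"`).
#' @param pos Optional integer positions per SNP.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "1", pos = NULL) {
  stopifnot(is.matrix(genotypes))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(nrow(genotypes)))
  if (is.null(pos)) pos <- seq_len(nrow(genotypes))
  gt <- matrix(c("0/0", "0/1", "1/1")[genotypes + 1L],
               nrow = nrow(genotypes))
  gt[is.na(genotypes)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(genotypes)), collapse = "\t")
  )
  body <- apply(cbind(chrom, pos, ids, "A", "C", ".", "PASS", ".", "GT", gt),
                1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from a minimal VCF written by [write_genotypes_vcf()]
#'
#' Requires the `vcfR` package. Multi-allelic records are an error.
#'
#' @param path VCF path.
#' @return SNP x patient 0/1/2/NA integer matrix.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (any(grepl(",", vcfR::getALT(v), fixed = TRUE)))
    stop("multi-allelic records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  counts[gt %in% c("0/0", "0|0")] <- 0L
  counts[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  counts[gt %in% c("1/1", "1|1")] <- 2L
  counts
}
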