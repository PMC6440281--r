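# Tab-delimited readers/writers for the genotype, expression, covariate and
# SNP-annotation tables, plus a minimal VCF import. Missing-dosage tokens
# accepted on read: NA, ".", "-9", "" (written back as a single "NA").

.missing_tokens <- c("NA", ".", "-9", "")

#' Read a genotype matrix
#'
#' Tab-delimited format: header `snp_id chrom pos <sample1> <sample2> ...`,
#' one SNP per row, dosage entries in \{0, 1, 2\} with `NA`, `.`, `-9` or an
#' empty field for missing. VCF v4 import (requires the `vcfR` package) keeps
#' biallelic records only and uses the genotype (GT) subfield, counting ALT
#' alleles; phased and unphased calls are both accepted.
#'
#' @param path file to read.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(read_genotypes_vcf(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(df)[1:3]))
    stop("genotype TSV must start with columns: snp_id, chrom, pos")
  sample_ids <- names(df)[-(1:3)]
  if (length(sample_ids) == 0L) stop("genotype TSV has no sample columns")
  raw <- as.matrix(df[, -(1:3), drop = FALSE])
  raw[raw %in% .missing_tokens] <- NA_character_
  bad <- !is.na(raw) & !(raw %in% c("0", "1", "2"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid dosage token '", raw[idx[1L], idx[2L]], "' for SNP '",
         df$snp_id[idx[1L]], "' (data line ", idx[1L], "), sample '",
         sample_ids[idx[2L]], "'")
  }
  dos <- matrix(as.numeric(raw), nrow = nrow(raw))
  genotype_matrix(dos, chrom = df$chrom, pos = as.integer(df$pos),
                  snp_ids = df$snp_id, sample_ids = sample_ids)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) & nchar(ref) >= 1L
  if (!any(biallelic)) stop("no biallelic records in VCF: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  count_alt <- function(cell) {
    if (is.na(cell) || cell %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(cell, "[/|]")[[1L]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }
  dos <- apply(gt, c(1, 2), count_alt)
  ids <- fix[biallelic, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[biallelic, "CHROM"][noid], ":", fix[biallelic, "POS"][noid])
  genotype_matrix(dos, chrom = fix[biallelic, "CHROM"],
                  pos = as.integer(fix[biallelic, "POS"]),
                  snp_ids = ids, sample_ids = colnames(gt))
}

#' Write a genotype matrix as TSV
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  dos <- g$dosages
  out <- matrix(as.character(dos), nrow = nrow(dos))
  out[is.na(dos)] <- "NA"
  df <- data.frame(snp_id = g$snp_ids, chrom = g$chrom, pos = g$pos,
                   out, check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("snp_id", "chrom", "pos", g$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Tab-delimited format: header `probe_id chrom start end <sample1> ...`.
#' Missing expression values are rejected at read time.
#'
#' @param path file to read.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!all(need %in% names(df)[1:4]))
    stop("expression TSV must start with columns: probe_id, chrom, start, end")
  vals <- as.matrix(df[, -(1:4), drop = FALSE])
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("missing expression value for probe '", df$probe_id[idx[1L]], "'")
  }
  expression_matrix(vals, chrom = as.character(df$chrom),
                    start = df$start, end = df$end,
                    probe_ids = df$probe_id,
                    sample_ids = colnames(vals))
}

#' Write an expression matrix as TSV
#' @param e an [expression_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(e, path) {
  df <- data.frame(probe_id = e$probe_ids, chrom = e$chrom,
                   start = e$start, end = e$end, e$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("probe_id", "chrom", "start", "end", e$sample_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a covariate table
#'
#' Tab-delimited format: header `sample_id <cov1> <cov2> ...`, one sample per
#' row; all covariates numeric (code categorical covariates such as sex as
#' 0/1 indicators upstream).
#'
#' @param path file to read.
#' @return A [covariate_table()].
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("covariate TSV must start with column: sample_id")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  covariate_table(vals, sample_ids = df$sample_id,
                  covariate_names = colnames(vals))
}

#' Write a covariate table as TSV
#' @param cv a [covariate_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cv, path) {
  df <- data.frame(sample_id = cv$sample_ids, cv$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", cv$covariate_names)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SNP annotation table for enrichment analysis
#'
#' Tab-delimited format: header `snp_id maf n_cis_genes trait_associated`;
#' `trait_associated` is 0/1 or TRUE/FALSE.
#'
#' @param path file to read.
#' @return A data frame with columns `snp_id`, `maf`, `n_cis_genes`,
#'   `trait_associated` (logical).
#' @export
read_snp_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  need <- c("snp_id", "maf", "n_cis_genes", "trait_associated")
  if (!all(need %in% names(df)))
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "))
  df$trait_associated <- as.logical(df$trait_associated)
  df$snp_id <- as.character(df$snp_id)
  if (any(df$maf <= 0 | df$maf > 0.5)) stop("annotation maf must lie in (0, 0.5]")
  if (any(df$n_cis_genes < 0)) stop("n_cis_genes must be nonnegative")
  df[, need]
}

#' Write a SNP annotation table
#' @param ann data frame as returned by [read_snp_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_annotation <- function(ann, path) {
  ann$trait_associated <- as.integer(ann$trait_associated)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
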