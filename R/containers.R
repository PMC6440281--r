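#' Construct a genotype matrix
#'
#' Bundles a SNP-by-sample dosage matrix with per-SNP genomic coordinates.
#' Dosages count copies of the coded allele (0, 1, 2) with `NA` for missing
#' calls; after [qc_filter()] the coding is guaranteed to be the minor allele.
#'
#' @param dosages numeric matrix, SNPs in rows, samples in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param chrom character vector of chromosome labels, one per SNP.
#' @param pos integer vector of 1-based base-pair positions, one per SNP.
#' @param snp_ids unique SNP identifiers; defaults to `rownames(dosages)`.
#' @param sample_ids unique sample identifiers; defaults to
#'   `colnames(dosages)`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `snp_ids`, `chrom`, `pos`, `dosages`, `sample_ids`. The dosage matrix
#'   carries the ids as dimnames.
#' @seealso [read_genotypes()], [qc_filter()], [dedup_complete_ld()]
#' @export
genotype_matrix <- function(dosages, chrom, pos, snp_ids = rownames(dosages),
                            sample_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(snp_ids)) stop("snp_ids are required (or set rownames on 'dosages')")
  if (is.null(sample_ids)) stop("sample_ids are required (or set colnames on 'dosages')")
  snp_ids <- as.character(snp_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosages) != length(snp_ids))
    stop("row count of dosages (", nrow(dosages), ") != number of snp_ids (",
         length(snp_ids), ")")
  if (ncol(dosages) != length(sample_ids))
    stop("column count of dosages != number of sample_ids")
  if (length(chrom) != length(snp_ids) || length(pos) != length(snp_ids))
    stop("chrom and pos must have one entry per SNP")
  if (anyDuplicated(snp_ids))
    stop("duplicate SNP id: ", snp_ids[duplicated(snp_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  bad <- !is.na(dosages) & !(dosages %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("dosage entries must be 0/1/2/NA; SNP '", snp_ids[idx[1L]],
         "', sample '", sample_ids[idx[2L]], "' has value ",
         dosages[idx[1L], idx[2L]])
  }
  dimnames(dosages) <- list(snp_ids, sample_ids)
  structure(
    list(snp_ids = snp_ids, chrom = as.character(chrom),
         pos = as.integer(pos), dosages = dosages, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$snp_ids), " SNPs x ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing rate: %.4f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Construct an expression matrix
#'
#' Probe-by-sample expression values with probe genomic intervals
#' (1-based, inclusive). Missing expression values are not allowed.
#'
#' @param values numeric matrix, probes in rows, samples in columns.
#' @param chrom chromosome label per probe.
#' @param start,end 1-based inclusive probe interval per probe.
#' @param probe_ids unique probe identifiers; defaults to `rownames(values)`.
#' @param sample_ids unique sample identifiers; defaults to `colnames(values)`.
#' @return An object of class `expression_matrix`.
#' @seealso [read_expression()], [quantile_normalize()]
#' @export
expression_matrix <- function(values, chrom, start, end,
                              probe_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids)) stop("probe_ids are required")
  if (is.null(sample_ids)) stop("sample_ids are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids))
    stop("row count of values != number of probe_ids")
  if (ncol(values) != length(sample_ids))
    stop("column count of values != number of sample_ids")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe id: ", probe_ids[duplicated(probe_ids)][1L])
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyNA(values)) stop("expression values must not contain missing entries")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start > end)) stop("probe interval start > end")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(
    list(probe_ids = probe_ids, chrom = as.character(chrom),
         start = start, end = end, values = values, sample_ids = sample_ids),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", length(x$probe_ids), " probes x ",
      length(x$sample_ids), " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a covariate table
#'
#' Sample-by-covariate matrix of real-valued covariates (sex indicator,
#' genotype principal components, precomputed expression factors, ...). The
#' full-rank requirement (after adding an intercept) is checked when a model
#' is fitted, not here. A table with zero covariates is valid.
#'
#' @param values numeric matrix, samples in rows, covariates in columns; a
#'   data frame is accepted and coerced.
#' @param sample_ids unique sample identifiers; defaults to `rownames(values)`.
#' @param covariate_names defaults to `colnames(values)`.
#' @return An object of class `covariate_table`.
#' @export
covariate_table <- function(values, sample_ids = rownames(values),
                            covariate_names = colnames(values)) {
  values <- as.matrix(values)
  if (ncol(values) > 0L) storage.mode(values) <- "double"
  if (is.null(sample_ids)) stop("sample_ids are required")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  if (nrow(values) != length(sample_ids))
    stop("row count of values != number of sample_ids")
  if (is.null(covariate_names)) covariate_names <- paste0("cov", seq_len(ncol(values)))
  if (anyNA(values)) stop("covariates must not contain missing entries")
  dimnames(values) <- list(sample_ids, covariate_names)
  structure(
    list(covariate_names = as.character(covariate_names), values = values,
         sample_ids = sample_ids),
    class = "covariate_table"
  )
}

#' An empty covariate table for a set of samples
#' @param sample_ids sample identifiers.
#' @return A `covariate_table` with zero covariate columns.
#' @export
empty_covariates <- function(sample_ids) {
  covariate_table(matrix(numeric(0), nrow = length(sample_ids), ncol = 0L,
                         dimnames = list(as.character(sample_ids), NULL)),
                  sample_ids = sample_ids, covariate_names = character(0))
}

#' @export
print.covariate_table <- function(x, ...) {
  cat("covariate_table: ", length(x$sample_ids), " samples x ",
      length(x$covariate_names), " covariates\n", sep = "")
  invisible(x)
}

# subset helpers (internal)
subset_genotypes <- function(g, snps = NULL, samples = NULL) {
  si <- if (is.null(snps)) seq_along(g$snp_ids) else snps
  pi <- if (is.null(samples)) seq_along(g$sample_ids) else samples
  genotype_matrix(g$dosages[si, pi, drop = FALSE], g$chrom[si], g$pos[si],
                  g$snp_ids[si], g$sample_ids[pi])
}

subset_expression <- function(e, probes = NULL, samples = NULL) {
  ri <- if (is.null(probes)) seq_along(e$probe_ids) else probes
  ci <- if (is.null(samples)) seq_along(e$sample_ids) else samples
  expression_matrix(e$values[ri, ci, drop = FALSE], e$chrom[ri],
                    e$start[ri], e$end[ri], e$probe_ids[ri], e$sample_ids[ci])
}

subset_covariates <- function(cv, samples) {
  covariate_table(cv$values[samples, , drop = FALSE],
                  cv$sample_ids[samples], cv$covariate_names)
}
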