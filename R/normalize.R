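# Expression normalization: across-sample quantile normalization and the
# rank-based inverse-normal transform.

#' Quantile-normalize an expression matrix across samples
#'
#' Classic microarray quantile normalization: each sample's empirical
#' distribution is replaced by the reference distribution formed by averaging
#' the per-rank sorted values across samples, so that afterwards the sorted
#' value vectors of all samples are identical. Ties within a sample receive
#' the mean of the reference values spanning their tied ranks. Delegates to
#' [limma::normalizeQuantiles()], the standard implementation of this
#' convention.
#'
#' @param e an [expression_matrix()] with at least two samples.
#' @return A quantile-normalized `expression_matrix` with unchanged probe
#'   annotation.
#' @export
quantile_normalize <- function(e) {
  if (length(e$sample_ids) < 2L)
    stop("quantile normalization needs at least 2 samples")
  norm <- limma::normalizeQuantiles(e$values, ties = TRUE)
  dimnames(norm) <- dimnames(e$values)
  expression_matrix(norm, e$chrom, e$start, e$end, e$probe_ids, e$sample_ids)
}

#' Rank-based inverse normal transform
#'
#' Maps a vector to standard-normal quantiles via Blom offsets:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with ties mid-ranked. Used so that
#' per-probe expression values approximately follow a normal distribution
#' before mediation testing.
#'
#' @param values numeric vector (one probe across samples), length >= 3.
#' @return Transformed vector of the same length.
#' @export
inverse_normal_transform <- function(values) {
  n <- length(values)
  if (n < 3L) stop("inverse normal transform needs at least 3 values")
  r <- rank(values, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}
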