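# Enrichment procedures: Fisher's exact test of trait-associated SNPs among
# mediated trans-eQTLs, and the MAF-matched permutation test for association
# with multiple cis-genes.

#' Fisher's exact test on a 2x2 contingency table
#'
#' Exact hypergeometric test; the two-sided p-value is the sum of
#' probabilities of all tables (with fixed margins) no more probable than
#' the observed one (the convention of [stats::fisher.test()], which performs
#' the computation). The reported odds ratio is the sample odds ratio
#' `(a d) / (b c)` (`Inf` when `b c = 0` with `a d > 0`), not the conditional
#' MLE. A table with an empty row or column margin carries no information:
#' p = 1 with `degenerate = TRUE`.
#'
#' @param a,b,c,d nonnegative counts: `a` = query & positive, `b` = query &
#'   negative, `c` = background & positive, `d` = background & negative.
#' @param alternative `"two_sided"` (default) or `"greater"` (enrichment
#'   one-sided).
#' @return A list: `odds_ratio`, `p`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (a + b < 1 || c + d < 1) stop("each row margin must be at least 1")
  if (a + c == 0 || b + d == 0 || a + b == 0 || c + d == 0)
    return(list(odds_ratio = NA_real_, p = 1, degenerate = TRUE))
  or <- if (b * c == 0) {
    if (a * d == 0) NA_real_ else Inf
  } else (a * d) / (b * c)
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                           alternative = if (alternative == "two_sided")
                             "two.sided" else "greater")
  list(odds_ratio = or, p = ft$p.value, degenerate = FALSE)
}

# bin index for MAF matching
.maf_bin <- function(maf, bin_width) as.integer(floor(maf / bin_width))

#' Sample a MAF-matched SNP set from a panel
#'
#' For each query SNP, one panel SNP is drawn from the same MAF bin
#' (half-open bins of width `bin_width`), without replacement within the
#' draw by default, so the sampled set has the query's MAF distribution at
#' bin resolution.
#'
#' @param query_mafs numeric vector of query SNP MAFs in (0, 0.5\].
#' @param panel data frame of panel SNP annotations with columns `snp_id`,
#'   `maf`, `n_cis_genes`, `trait_associated` (see [read_snp_annotation()]).
#' @param bin_width MAF bin width (default 0.05).
#' @param replace sample with replacement within bins (for small panels).
#' @return The sampled rows of `panel` (one per query SNP).
#' @export
maf_matched_resample <- function(query_mafs, panel, bin_width = 0.05,
                                 replace = FALSE) {
  qbin <- .maf_bin(query_mafs, bin_width)
  pbin <- .maf_bin(panel$maf, bin_width)
  need <- table(qbin)
  picked <- integer(0)
  for (b in names(need)) {
    pool <- which(pbin == as.integer(b))
    k <- need[[b]]
    if (length(pool) == 0L || (!replace && length(pool) < k))
      stop("panel has too few SNPs in MAF bin [",
           as.integer(b) * bin_width, ", ", (as.integer(b) + 1) * bin_width,
           "): need ", k, ", have ", length(pool))
    picked <- c(picked, pool[sample.int(length(pool), k, replace = replace)])
  }
  panel[picked, , drop = FALSE]
}

#' MAF-matched permutation test of multi-cis-gene association
#'
#' Tests whether a query SNP set (e.g. trans-eQTLs) is enriched for SNPs
#' associated with multiple cis-genes, against a background panel. The
#' observed statistic is the proportion of query SNPs with at least two
#' (`"prop_ge2_cis"`, default) or at least one (`"prop_ge1_cis"`)
#' cis-associated genes. Each of `B` permutation draws samples a MAF-matched
#' SNP set of the same size from the panel and recomputes the statistic; the
#' empirical p-value is `(1 + #\{draws >= observed\}) / (B + 1)`.
#'
#' @param query data frame of query SNP annotations (same columns as
#'   `panel`).
#' @param panel data frame of background SNP annotations.
#' @param statistic `"prop_ge2_cis"` or `"prop_ge1_cis"`.
#' @param B number of resampling draws (default 1000).
#' @param seed optional integer seed.
#' @param bin_width MAF bin width for matching (default 0.05).
#' @param replace passed to [maf_matched_resample()].
#' @return A list: `observed`, `p`, `B`, `statistic`, `null_stats`.
#' @export
permutation_enrichment_test <- function(query, panel,
                                        statistic = c("prop_ge2_cis",
                                                      "prop_ge1_cis"),
                                        B = 1000L, seed = NULL,
                                        bin_width = 0.05, replace = FALSE) {
  statistic <- match.arg(statistic)
  if (nrow(query) == 0L) stop("query must contain at least one SNP")
  thr <- if (statistic == "prop_ge2_cis") 2L else 1L
  stat_fn <- function(ann) mean(ann$n_cis_genes >= thr)
  obs <- stat_fn(query)
  if (!is.null(seed)) set.seed(seed)
  null_stats <- vapply(seq_len(B), function(i)
    stat_fn(maf_matched_resample(query$maf, panel, bin_width, replace)),
    numeric(1))
  p <- (1 + sum(null_stats >= obs)) / (B + 1)
  list(observed = obs, p = p, B = B, statistic = statistic,
       null_stats = null_stats)
}
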