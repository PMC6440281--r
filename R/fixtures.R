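# Seeded synthetic-fixture generators: genotype/expression/covariate/
# annotation tables with planted cis effects, mediated trans effects and
# correlated mediator noise, laid out on two synthetic chromosomes so that
# the 1 Mb cis window and the inter-chromosomal trans logic are both
# exercised. Every other module is testable from these without any external
# download.

#' Specify a synthetic fixture
#'
#' @param n_samples number of samples.
#' @param n_snps number of SNPs, laid out alternately on two synthetic
#'   chromosomes at 3 Mb spacing (so distinct SNPs are never within one cis
#'   window of each other's probes).
#' @param maf_range range the per-SNP minor allele frequency is drawn from
#'   (uniform; default c(0.10, 0.50)).
#' @param missing_rate per-entry genotype missingness (default 0).
#' @param planted_trios list of lists, each with elements `snp` (SNP index),
#'   `alphaX` (vector, one cis effect per mediator), `betaM` (same length),
#'   `betaX` (direct effect) and `rho` (mediator error correlation).
#'   Defaults chosen for desk-scale power: `alphaX = c(0.8, 0.8)`,
#'   `betaM = c(0.3, 0.3)`, `betaX = 0.3`, `rho = 0.2`.
#' @param planted_direct_trans list of lists with `snp` and `effect`: a
#'   trans association with no mediation (the trans-gene responds to the SNP
#'   directly, not through any cis-gene).
#' @param n_null_probes pure-noise probes scattered over both chromosomes.
#' @param seed integer seed; the whole bundle is a deterministic function of
#'   the fixture specification including this seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_samples = 300L, n_snps = 6L,
                         maf_range = c(0.10, 0.50), missing_rate = 0,
                         planted_trios = list(), planted_direct_trans = list(),
                         n_null_probes = 10L, seed = 1L) {
  stopifnot(n_samples >= 10L, n_snps >= 1L,
            maf_range[1] >= 0.05, maf_range[2] <= 0.5,
            missing_rate >= 0, missing_rate < 1)
  for (t in planted_trios) {
    stopifnot(t$snp >= 1L, t$snp <= n_snps,
              length(t$alphaX) == length(t$betaM),
              abs(t$rho %||% 0.2) < 1)
  }
  for (d in planted_direct_trans) stopifnot(d$snp >= 1L, d$snp <= n_snps)
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 maf_range = maf_range, missing_rate = missing_rate,
                 planted_trios = planted_trios,
                 planted_direct_trans = planted_direct_trans,
                 n_null_probes = as.integer(n_null_probes),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default planted-trio parameters
#'
#' Effect sizes large enough for reliable detection at a few hundred
#' samples (distinct from the simulation study's deliberately marginal
#' effects).
#' @param snp SNP index.
#' @param p number of mediators.
#' @return A planted-trio list for [fixture_spec()].
#' @export
planted_trio <- function(snp = 1L, p = 2L) {
  list(snp = snp, alphaX = rep(0.8, p), betaM = rep(0.3, p),
       betaX = 0.3, rho = 0.2)
}

# chromosome / position layout: SNP i alternates chr1/chr2, 3 Mb apart
.snp_layout <- function(n_snps) {
  list(chrom = paste0("chr", 1L + (seq_len(n_snps) - 1L) %% 2L),
       pos = as.integer(2e6 + ((seq_len(n_snps) - 1L) %/% 2L) * 3e6))
}

#' Generate a synthetic genotype matrix
#'
#' Per SNP: MAF drawn uniformly from `maf_range`, dosages Binomial(2, MAF)
#' (Hardy-Weinberg proportions), missing entries at `missing_rate`.
#'
#' @param spec a [fixture_spec()].
#' @return A [genotype_matrix()] with an attribute `true_maf`.
#' @export
generate_genotype_matrix <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples; s <- spec$n_snps
  maf <- stats::runif(s, spec$maf_range[1], spec$maf_range[2])
  dos <- matrix(stats::rbinom(s * n, 2L, rep(maf, n)), nrow = s)
  if (spec$missing_rate > 0)
    dos[stats::runif(s * n) < spec$missing_rate] <- NA_real_
  lay <- .snp_layout(s)
  g <- genotype_matrix(dos, lay$chrom, lay$pos,
                       snp_ids = sprintf("snp%03d", seq_len(s)),
                       sample_ids = sprintf("sample%03d", seq_len(n)))
  attr(g, "true_maf") <- maf
  g
}

#' Generate synthetic expression with planted structure
#'
#' Mediator probes are placed within the cis window of their SNP (same
#' chromosome, 200 kb away); each planted trans-gene probe goes on the other
#' chromosome. Mediators follow the forward mediation model
#' `M_j = 0.5 + alphaX_j X + eps_Mj` with exchangeable error correlation
#' `rho`, and the trans-gene is `Y = 0.5 + betaX X + sum_j betaM_j M_j +
#' eps_Y`. Direct-only trans probes use `Y = 0.5 + effect X + eps` (no
#' mediator term). Null probes are standard normal noise scattered over both
#' chromosomes. Missing dosages do not propagate: the forward model uses the
#' complete (pre-missingness) dosage when available, otherwise the mean
#' imputation of that SNP — expression data carry no missing values.
#'
#' @param spec a [fixture_spec()].
#' @param g the [generate_genotype_matrix()] output for `spec`.
#' @return An [expression_matrix()]; probe ids encode their role
#'   (`med<t>_<j>`, `trans<t>`, `direct<k>`, `null<i>`).
#' @export
generate_expression <- function(spec, g) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(g, "genotype_matrix"))
  set.seed(spec$seed + 1L)
  n <- spec$n_samples
  probes <- list()
  add_probe <- function(id, chrom, center, values)
    probes[[length(probes) + 1L]] <<- list(id = id, chrom = chrom,
                                           start = as.integer(center),
                                           end = as.integer(center + 999L),
                                           values = values)
  snp_x <- function(si) {
    x <- g$dosages[si, ]
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }
  other_chrom <- function(ch) if (ch == "chr1") "chr2" else "chr1"

  for (t in seq_along(spec$planted_trios)) {
    tr <- spec$planted_trios[[t]]
    si <- tr$snp
    x <- snp_x(si)
    p <- length(tr$alphaX)
    rho <- tr$rho %||% 0.2
    R <- matrix(rho, p, p); diag(R) <- 1
    L <- chol(R)
    eps <- matrix(stats::rnorm(n * p), n, p) %*% L
    M <- matrix(0, n, p)
    for (j in seq_len(p)) M[, j] <- 0.5 + tr$alphaX[j] * x + eps[, j]
    Y <- 0.5 + (tr$betaX %||% 0.3) * x + drop(M %*% tr$betaM) + stats::rnorm(n)
    for (j in seq_len(p))
      add_probe(sprintf("med%d_%d", t, j), g$chrom[si],
                g$pos[si] + 2e5 + (j - 1L) * 5e3, M[, j])
    add_probe(sprintf("trans%d", t), other_chrom(g$chrom[si]),
              g$pos[si] + 1e6, Y)
  }
  for (k in seq_along(spec$planted_direct_trans)) {
    d <- spec$planted_direct_trans[[k]]
    x <- snp_x(d$snp)
    Y <- 0.5 + d$effect * x + stats::rnorm(n)
    add_probe(sprintf("direct%d", k), other_chrom(g$chrom[d$snp]),
              g$pos[d$snp] + 1.5e6, Y)
  }
  if (spec$n_null_probes > 0L) {
    max_pos <- max(g$pos) + 5e6
    for (i in seq_len(spec$n_null_probes))
      add_probe(sprintf("null%d", i), paste0("chr", 1L + i %% 2L),
                stats::runif(1, 1e5, max_pos), stats::rnorm(n))
  }
  if (length(probes) == 0L) stop("fixture spec yields no probes")
  expression_matrix(
    do.call(rbind, lapply(probes, `[[`, "values")),
    chrom = vapply(probes, `[[`, character(1), "chrom"),
    start = vapply(probes, `[[`, integer(1), "start"),
    end = vapply(probes, `[[`, integer(1), "end"),
    probe_ids = vapply(probes, `[[`, character(1), "id"),
    sample_ids = g$sample_ids)
}

#' Generate a synthetic SNP annotation panel for enrichment tests
#'
#' @param n_snps panel size.
#' @param trait_fraction marginal probability a panel SNP is
#'   trait-associated.
#' @param cis_count_distribution probability vector over cis-gene counts
#'   0, 1, 2, ... (default `c(0.90, 0.07, 0.03)`).
#' @param seed integer seed.
#' @param maf_range MAF range, drawn uniformly (default c(0.05, 0.5)).
#' @return A data frame with columns `snp_id`, `maf`, `n_cis_genes`,
#'   `trait_associated`.
#' @export
generate_annotation_panel <- function(n_snps, trait_fraction = 0.014,
                                      cis_count_distribution = c(0.90, 0.07, 0.03),
                                      seed = 1L, maf_range = c(0.05, 0.5)) {
  stopifnot(trait_fraction >= 0, trait_fraction <= 1,
            all(cis_count_distribution >= 0),
            abs(sum(cis_count_distribution) - 1) < 1e-8)
  set.seed(seed)
  data.frame(
    snp_id = sprintf("panel%06d", seq_len(n_snps)),
    maf = stats::runif(n_snps, maf_range[1], maf_range[2]),
    n_cis_genes = sample(seq_along(cis_count_distribution) - 1L, n_snps,
                         replace = TRUE, prob = cis_count_distribution),
    trait_associated = stats::runif(n_snps) < trait_fraction,
    stringsAsFactors = FALSE)
}

#' Write a complete fixture bundle to disk
#'
#' Writes `genotypes.tsv`, `expression.tsv`, `covariates.tsv` (with a
#' synthetic 0/1 sex column, mirroring the convention of including sex as a
#' covariate), and `manifest.yaml` recording the specification and seed so the bundle
#' can be regenerated byte-identically.
#'
#' @param spec a [fixture_spec()].
#' @param out_dir output directory (created if needed).
#' @return Named character vector of the written file paths, invisibly.
#' @export
write_fixture_bundle <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- generate_genotype_matrix(spec)
  e <- generate_expression(spec, g)
  set.seed(spec$seed + 2L)
  cv <- covariate_table(
    matrix(stats::rbinom(spec$n_samples, 1L, 0.5), ncol = 1L,
           dimnames = list(g$sample_ids, "sex")),
    sample_ids = g$sample_ids)
  paths <- c(genotypes = file.path(out_dir, "genotypes.tsv"),
             expression = file.path(out_dir, "expression.tsv"),
             covariates = file.path(out_dir, "covariates.tsv"),
             manifest = file.path(out_dir, "manifest.yaml"))
  write_genotypes(g, paths["genotypes"])
  write_expression(e, paths["expression"])
  write_covariates(cv, paths["covariates"])
  manifest <- c(
    "# synthetic fixture manifest (regenerate with write_fixture_bundle)",
    paste0("seed: ", spec$seed),
    paste0("n_samples: ", spec$n_samples),
    paste0("n_snps: ", spec$n_snps),
    paste0("maf_range: [", spec$maf_range[1], ", ", spec$maf_range[2], "]"),
    paste0("missing_rate: ", spec$missing_rate),
    paste0("n_null_probes: ", spec$n_null_probes),
    paste0("n_planted_trios: ", length(spec$planted_trios)),
    paste0("n_planted_direct_trans: ", length(spec$planted_direct_trans)))
  writeLines(manifest, paths["manifest"])
  invisible(paths)
}
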