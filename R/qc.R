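# Genotype quality control: minor allele frequency, exact Hardy-Weinberg
# test, sample/SNP filters, and complete-LD deduplication.

#' Minor allele frequency of one SNP
#'
#' @param dosages dosage vector in \{0, 1, 2, NA\}.
#' @return `min(f, 1 - f)` where `f` is the coded-allele frequency over
#'   non-missing entries; always in \[0, 0.5\].
#' @export
compute_maf <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("all dosages missing; MAF undefined")
  f <- sum(dosages[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test: given the observed allele counts, the number of
#' heterozygotes follows a known discrete distribution under HWE; the p-value
#' is the sum of probabilities of all heterozygote counts no more likely than
#' the observed one. The exact test is used (rather than the chi-square
#' approximation) because the filtering threshold of interest, 1e-5, sits far
#' in the tail where the chi-square approximation is unreliable.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (reference homozygote,
#'   heterozygote, alternate homozygote).
#' @return Exact p-value in (0, 1\].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (any(c(n_hom_ref, n_het, n_hom_alt) < 0)) stop("genotype counts must be nonnegative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("at least one genotyped sample required")
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  probs <- .hwe_het_distribution(n, n_minor)      # indexed by heterozygote count
  p_obs <- probs[as.character(n_het)]
  if (is.na(p_obs)) stop("heterozygote count incompatible with allele counts")
  # standard relative tolerance guards ties against floating-point noise
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# P(het = h | n individuals, n_minor minor alleles) under HWE, for all
# feasible h (same parity as n_minor). Log-scale for numerical stability.
.hwe_het_distribution <- function(n, n_minor) {
  n_major <- 2 * n - n_minor
  h <- seq.int(n_minor %% 2, min(n_minor, n_major), by = 2)
  hom_min <- (n_minor - h) / 2
  hom_maj <- n - h - hom_min
  lp <- lfactorial(n) - lfactorial(hom_min) - lfactorial(h) - lfactorial(hom_maj) +
    h * log(2) + lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2 * n)
  p <- exp(lp)
  names(p) <- as.character(h)
  p / sum(p)
}

#' Per-SNP genotype counts
#' @param dosages dosage vector.
#' @return Named counts `n0`, `n1`, `n2` over non-missing entries.
#' @export
genotype_counts <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  c(n0 = sum(d == 0), n1 = sum(d == 1), n2 = sum(d == 2))
}

#' Recode dosages so that every SNP counts its minor allele
#'
#' SNPs whose coded-allele frequency exceeds 0.5 are flipped (x -> 2 - x).
#' Downstream effect estimates are therefore expressed per copy of the minor
#' allele for every SNP.
#'
#' @param g a [genotype_matrix()].
#' @return A `genotype_matrix` with the same SNPs, minor-allele coded, plus an
#'   attribute `flipped` (logical per SNP).
#' @export
orient_minor_allele <- function(g) {
  f <- apply(g$dosages, 1L, function(d) {
    ok <- !is.na(d)
    if (!any(ok)) return(0)
    sum(d[ok]) / (2 * sum(ok))
  })
  flip <- f > 0.5
  dos <- g$dosages
  dos[flip, ] <- 2 - dos[flip, , drop = FALSE]
  out <- genotype_matrix(dos, g$chrom, g$pos, g$snp_ids, g$sample_ids)
  attr(out, "flipped") <- flip
  out
}

#' Genotype quality-control filter
#'
#' Filters are applied in order: (1) samples with call rate below
#' `sample_call_rate_min` are removed; then, on the retained samples, SNPs are
#' removed if (2) their missing rate is `snp_missing_max` or higher, (3) their
#' MAF is not strictly greater than `maf_min`, or (4) their exact
#' Hardy-Weinberg p-value is below `hwe_p_min`. Retained SNPs are recoded to
#' minor-allele dosages ([orient_minor_allele()]).
#'
#' @param g a [genotype_matrix()].
#' @param sample_call_rate_min minimum sample call rate (default 0.97).
#' @param snp_missing_max maximum SNP missing rate, exclusive (default 0.08).
#' @param maf_min MAF threshold, exclusive (default 0.10): a SNP at exactly
#'   `maf_min` is removed.
#' @param hwe_p_min Hardy-Weinberg exact p-value threshold (default 1e-5):
#'   SNPs with p below it are removed.
#' @return A list with `genotypes` (the filtered, minor-allele-coded matrix)
#'   and `report`, itself a list of two data frames: `snps` (per-SNP
#'   `call_rate`, `maf`, `hwe_p`, `pass`, `fail_reason`) and `samples`
#'   (per-sample `call_rate`, `pass`).
#' @export
qc_filter <- function(g, sample_call_rate_min = 0.97, snp_missing_max = 0.08,
                      maf_min = 0.10, hwe_p_min = 1e-5) {
  stopifnot(sample_call_rate_min >= 0, sample_call_rate_min <= 1,
            snp_missing_max >= 0, snp_missing_max <= 1,
            maf_min >= 0, maf_min <= 0.5, hwe_p_min >= 0, hwe_p_min <= 1)
  sample_cr <- colMeans(!is.na(g$dosages))
  keep_sample <- sample_cr >= sample_call_rate_min
  sample_report <- data.frame(sample_id = g$sample_ids, call_rate = sample_cr,
                              pass = keep_sample, stringsAsFactors = FALSE)
  g2 <- subset_genotypes(g, samples = which(keep_sample))

  n_snp <- length(g2$snp_ids)
  miss <- rowMeans(is.na(g2$dosages))
  call_rate <- 1 - miss
  maf <- numeric(n_snp); hwe_p <- rep(NA_real_, n_snp)
  fail <- rep(NA_character_, n_snp)
  for (i in seq_len(n_snp)) {
    d <- g2$dosages[i, ]
    if (all(is.na(d))) { maf[i] <- NA_real_; fail[i] <- "missingness"; next }
    maf[i] <- compute_maf(d)
    if (miss[i] >= snp_missing_max) { fail[i] <- "missingness"; next }
    if (!(maf[i] > maf_min)) { fail[i] <- "maf"; next }
    cnt <- genotype_counts(d)
    hwe_p[i] <- hwe_exact_test(cnt["n0"], cnt["n1"], cnt["n2"])
    if (hwe_p[i] < hwe_p_min) fail[i] <- "hwe"
  }
  pass <- is.na(fail)
  snp_report <- data.frame(snp_id = g2$snp_ids, call_rate = call_rate,
                           maf = maf, hwe_p = hwe_p, pass = pass,
                           fail_reason = fail, stringsAsFactors = FALSE)
  if (!any(pass) || !any(keep_sample))
    warning("quality control removed every SNP or every sample")
  g_out <- orient_minor_allele(subset_genotypes(g2, snps = which(pass)))
  list(genotypes = g_out,
       report = list(snps = snp_report, samples = sample_report))
}

#' Remove duplicate SNPs in complete linkage disequilibrium
#'
#' Among any group of SNPs with pairwise r-squared equal to 1 (computed on
#' shared non-missing samples) or mapped to the same (chromosome, position),
#' exactly one representative is retained. The default representative is
#' deterministic — lowest position, ties broken by lexicographic SNP id — so
#' repeated runs give identical output; set `random = TRUE` (with a seed) to
#' pick the representative uniformly at random instead.
#'
#' @param g a [genotype_matrix()].
#' @param random pick group representatives at random instead of
#'   deterministically.
#' @param seed optional seed used when `random = TRUE`.
#' @return A `genotype_matrix` with one representative per complete-LD group.
#' @export
dedup_complete_ld <- function(g, random = FALSE, seed = NULL) {
  n <- length(g$snp_ids)
  if (n <= 1L) return(g)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  # identical (chrom, pos)
  key <- paste(g$chrom, g$pos, sep = ":")
  for (grp in split(seq_len(n), key)) {
    if (length(grp) > 1L) for (j in grp[-1L]) union_(grp[1L], j)
  }
  # pairwise complete-LD within chromosome; r^2 on shared non-missing samples
  for (ch in unique(g$chrom)) {
    idx <- which(g$chrom == ch)
    if (length(idx) < 2L) next
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in seq.int(a + 1L, length(idx))) {
        i <- idx[a]; j <- idx[b]
        if (find(i) == find(j)) next
        di <- g$dosages[i, ]; dj <- g$dosages[j, ]
        ok <- !is.na(di) & !is.na(dj)
        if (sum(ok) < 2L) next
        vi <- di[ok]; vj <- dj[ok]
        if (stats::sd(vi) == 0 || stats::sd(vj) == 0) next
        r <- stats::cor(vi, vj)
        if (abs(r) >= 1 - 1e-9) union_(i, j)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  if (random && !is.null(seed)) set.seed(seed)
  keep <- vapply(split(seq_len(n), roots), function(members) {
    if (length(members) == 1L) return(members)
    if (random) return(members[sample.int(length(members), 1L)])
    members[order(g$pos[members], g$snp_ids[members])[1L]]
  }, integer(1))
  subset_genotypes(g, snps = sort(unname(keep)))
}
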