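# Independent brute-force oracles and small data builders shared by the
# tests. The oracles deliberately avoid the package's internal code paths:
# direct factorial products for the Hardy-Weinberg and hypergeometric
# distributions, explicit normal equations for least squares, and the
# classic step-up formulation of Benjamini-Hochberg.

# exact HWE p by direct enumeration with plain factorial products
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  n_major <- 2 * n - n_minor
  hs <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  w <- vapply(hs, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    factorial(n) / (factorial(hom_min) * factorial(h) * factorial(hom_maj)) * 2^h
  }, numeric(1))
  pr <- w / sum(w)
  p_obs <- pr[match(n_het, hs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins
fisher_oracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0L, k - n2); hi <- min(k, m)
  xs <- lo:hi
  pr <- vapply(xs, function(x)
    choose(m, x) * choose(n2, k - x) / choose(m + n2, k), numeric(1))
  p_obs <- pr[match(a, xs)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# effect/stderr/t/p of the x coefficient by explicit normal equations
ols_oracle <- function(y, x, C = NULL) {
  D <- cbind(1, x, C)
  XtX <- t(D) %*% D
  beta <- solve(XtX, t(D) %*% y)
  res <- y - D %*% beta
  df <- length(y) - ncol(D)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * solve(XtX)[2, 2])
  tt <- beta[2] / se
  list(effect = beta[2], stderr = se, t = tt,
       p = 2 * pt(abs(tt), df, lower.tail = FALSE))
}

# classic BH step-up rejection set at level alpha
bh_reject_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= alpha * seq_len(m) / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# a small genotype matrix laid out on two chromosomes
toy_genotypes <- function(dos, chrom = NULL, pos = NULL) {
  dos <- as.matrix(dos)
  s <- nrow(dos)
  genotype_matrix(dos,
                  chrom = chrom %||% rep("chr1", s),
                  pos = pos %||% as.integer(seq_len(s) * 1e6),
                  snp_ids = paste0("s", seq_len(s)),
                  sample_ids = paste0("ind", seq_len(ncol(dos))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulated mediation data drawn outside the package's generator
draw_mediation_data <- function(n = 100, alphaX = c(0.6, 0.6),
                                betaM = c(0, 0), betaX = 0.3, rho = 0.2,
                                maf = 0.3) {
  repeat {
    X <- rbinom(n, 2, maf)
    if (var(X) > 0) break
  }
  z1 <- rnorm(n); z2 <- rnorm(n)
  e1 <- z1; e2 <- rho * z1 + sqrt(1 - rho^2) * z2
  M <- cbind(0.5 + alphaX[1] * X + e1, 0.5 + alphaX[2] * X + e2)
  Y <- 0.5 + betaX * X + drop(M %*% betaM) + rnorm(n)
  mediation_data(Y, X, M)
}
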