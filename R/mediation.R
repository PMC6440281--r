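# Multi-mediator mediation model and bootstrap tests.
#
# For a trio (SNP X, cis-mediators M_1..M_p, trans-gene Y) with covariates C,
# the joint model is
#   Y   = beta0 + X betaX + M' betaM + C' betaC + eps_Y,   eps_Y ~ N(0, sigma^2)
#   M_j = alpha0_j + X alphaX_j + C' alphaC_j + eps_M_j,   eps_M  ~ N_p(0, Sigma)
# with eps_Y independent of eps_M but free correlation among mediator errors
# (off-diagonal Sigma). The estimands are the total mediation effect
# Delta = alphaX' betaM and the component-wise effects delta_j =
# alphaX_j betaM_j; Delta = sum_j delta_j by construction. Significance is
# assessed by nonparametric case-resampling bootstrap with a two-sided
# percentile p-value.

#' Assemble data for one mediation trio
#'
#' @param Y numeric trans-gene expression vector (length n).
#' @param X numeric dosage vector (length n), no missing values (assemble
#'   complete cases upstream), non-constant.
#' @param M numeric matrix (n x p) of mediator expression, p >= 1.
#' @param C optional covariate matrix (n x q) or [covariate_table()].
#' @return An object of class `mediation_data`.
#' @export
mediation_data <- function(Y, X, M, C = NULL) {
  M <- as.matrix(M)
  Cm <- if (is.null(C)) matrix(numeric(0), length(Y), 0L)
        else if (inherits(C, "covariate_table")) C$values else as.matrix(C)
  n <- length(Y); p <- ncol(M); q <- ncol(Cm)
  if (length(X) != n || nrow(M) != n || nrow(Cm) != n)
    stop("Y, X, M, C must have matching sample counts")
  if (anyNA(Y) || anyNA(X) || anyNA(M) || (q > 0 && anyNA(Cm)))
    stop("mediation data must be complete-case (no missing values)")
  if (p < 1L) stop("at least one mediator is required")
  if (n <= p + q + 2L)
    stop("need n > p + q + 2 (n = ", n, ", p = ", p, ", q = ", q, ")")
  if (stats::var(X) == 0) stop("X is constant; mediation model undefined")
  if (is.null(colnames(M))) colnames(M) <- paste0("M", seq_len(p))
  structure(list(Y = as.numeric(Y), X = as.numeric(X), M = M, C = Cm,
                 n = n, p = p, q = q),
            class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat("mediation_data: n = ", x$n, ", mediators p = ", x$p,
      ", covariates q = ", x$q, "\n", sep = "")
  invisible(x)
}

#' Fit the joint multi-mediator mediation model
#'
#' Two stages of ordinary least squares: the outcome stage regresses Y on
#' \[1, X, M, C\]; the mediator stage regresses each M_j on \[1, X, C\].
#' The mediator residual covariance `Sigma` (divisor n - q - 2) is estimated
#' with free off-diagonals, allowing dependence among cis-gene errors.
#'
#' @param data a [mediation_data()].
#' @return An object of class `mediation_fit` with elements `beta0`, `betaX`,
#'   `betaM` (length p), `betaC` (length q), `alpha0`, `alphaX` (length p),
#'   `alphaC` (q x p), `sigma2` (outcome residual variance, divisor
#'   n - p - q - 2), `Sigma` (p x p), and `data`.
#' @export
fit_mediation <- function(data) {
  stopifnot(inherits(data, "mediation_data"))
  n <- data$n; p <- data$p; q <- data$q
  Dout <- cbind(`(Intercept)` = 1, X = data$X, data$M, data$C)
  out <- .ols(Dout, data$Y)
  Dmed <- cbind(`(Intercept)` = 1, X = data$X, data$C)
  med <- .ols(Dmed, data$M)
  A <- med$coef                      # (2+q) x p
  res_M <- med$resid
  Sigma <- crossprod(res_M) / (n - q - 2)
  structure(list(
    beta0 = unname(out$coef[1L]), betaX = unname(out$coef[2L]),
    betaM = unname(out$coef[seq.int(3L, 2L + p)]),
    betaC = if (q > 0) unname(out$coef[seq.int(3L + p, 2L + p + q)]) else numeric(0),
    alpha0 = unname(A[1L, ]), alphaX = unname(A[2L, ]),
    alphaC = if (q > 0) unname(A[seq.int(3L, 2L + q), , drop = FALSE])
             else matrix(numeric(0), 0L, p),
    sigma2 = out$rss / (n - p - q - 2),
    Sigma = unname(Sigma),
    data = data), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat("mediation_fit (p = ", length(x$betaM), " mediators)\n", sep = "")
  cat("  alphaX:", signif(x$alphaX, 4), "\n")
  cat("  betaM: ", signif(x$betaM, 4), "\n")
  cat("  TME:   ", signif(tme(x), 4), "\n")
  invisible(x)
}

#' Total mediation effect
#'
#' `Delta = alphaX' betaM`, the sum over mediators of the
#' product-of-coefficients indirect effects.
#' @param fit a [fit_mediation()] result.
#' @return Scalar estimate; equals `sum(cme(fit))` exactly.
#' @export
tme <- function(fit) sum(cme(fit))

#' Component-wise mediation effects
#'
#' `delta_j = alphaX_j betaM_j`, one indirect effect per mediator.
#' @param fit a [fit_mediation()] result.
#' @return Numeric vector of length p.
#' @export
cme <- function(fit) {
  stopifnot(inherits(fit, "mediation_fit"))
  fit$alphaX * fit$betaM
}

# two-sided percentile bootstrap p from the resampled statistic values
.percentile_p <- function(stat_star) {
  B <- length(stat_star)
  lo <- (1 + sum(stat_star <= 0)) / (B + 1)
  hi <- (1 + sum(stat_star >= 0)) / (B + 1)
  min(1, 2 * min(lo, hi))
}

# n x B matrix of case-resampling indices; columns on which X would be
# constant are redrawn so every resample admits the model fit.
.boot_indices <- function(n, B, X, max_redraw = 1000L) {
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
  redraws <- 0L
  repeat {
    const <- which(apply(idx, 2L, function(i) {
      xi <- X[i]
      all(xi == xi[1L])
    }))
    if (length(const) == 0L) break
    redraws <- redraws + length(const)
    if (redraws > max_redraw)
      stop("could not draw non-degenerate bootstrap resamples (X nearly constant)")
    idx[, const] <- sample.int(n, n * length(const), replace = TRUE)
  }
  attr(idx, "redraws") <- redraws
  idx
}

# shared driver: resample, compute statistics in compiled code
.boot_stats <- function(data, B, include_sme) {
  idx <- .boot_indices(data$n, B, data$X)
  st <- boot_mediation_stats(data$Y, data$X, data$M, data$C, idx, include_sme)
  st$redraws <- attr(idx, "redraws")
  st
}

.new_test_result <- function(test, estimate, p_value, component_p, B, seed,
                             redraws) {
  structure(list(test = test, estimate = estimate, p_value = p_value,
                 component_p = component_p, B = B, seed = seed,
                 redraws = redraws),
            class = "mediation_test_result")
}

#' @export
print.mediation_test_result <- function(x, ...) {
  cat(x$test, " bootstrap test (B = ", x$B, ")\n", sep = "")
  cat("  estimate:", signif(x$estimate, 4), "\n")
  cat("  p-value: ", format.pval(x$p_value, digits = 4), "\n")
  if (!is.null(x$component_p))
    cat("  component p:", format.pval(x$component_p, digits = 4), "\n")
  invisible(x)
}

#' Bootstrap test of the total mediation effect (TME)
#'
#' Tests H0: Delta = 0 by nonparametric case resampling: whole rows
#' (Y, X, M, C) are resampled with replacement, Delta* is recomputed on each
#' resample, and the two-sided percentile p-value is
#' `min(1, 2 min((1 + #\{Delta* <= 0\}) / (B + 1), (1 + #\{Delta* >= 0\}) / (B + 1)))`,
#' which is bounded below by 1/(B+1). Resamples on which X is constant are
#' redrawn (count reported).
#'
#' @param data a [mediation_data()].
#' @param B number of bootstrap resamples (>= 100; default 1000).
#' @param seed optional integer seed for the resampling stream.
#' @return A `mediation_test_result` with `test = "TME"`, the point estimate
#'   `Delta`, and `p_value`.
#' @export
bootstrap_test_tme <- function(data, B = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mediation_data"), B >= 100L)
  if (!is.null(seed)) set.seed(seed)
  est <- tme(fit_mediation(data))
  st <- .boot_stats(data, B, include_sme = FALSE)
  .new_test_result("TME", est, .percentile_p(st$Delta), NULL, B, seed,
                   st$redraws)
}

#' Bootstrap test of the component-wise mediation effects (CME)
#'
#' Tests H0: delta = 0 (every component zero). Each component delta_j gets a
#' two-sided percentile bootstrap p-value from the same case resamples; the
#' overall p-value is the Bonferroni combination `min(1, p min_j p_j)`. With
#' a single mediator this reduces exactly to the TME test. The CME null is
#' narrower than the TME null: component effects of opposite sign that cancel
#' in the sum leave Delta = 0 while delta != 0, which is where this test
#' gains power.
#'
#' @inheritParams bootstrap_test_tme
#' @return A `mediation_test_result` with `test = "CME"`, `estimate` the
#'   delta vector, `p_value` the Bonferroni-combined p, and `component_p`.
#' @export
bootstrap_test_cme <- function(data, B = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mediation_data"), B >= 100L)
  if (!is.null(seed)) set.seed(seed)
  est <- cme(fit_mediation(data))
  st <- .boot_stats(data, B, include_sme = FALSE)
  comp_p <- apply(st$delta, 2L, .percentile_p)
  .new_test_result("CME", est, min(1, data$p * min(comp_p)), comp_p, B, seed,
                   st$redraws)
}

#' Bootstrap test of a single mediation effect (SME)
#'
#' Fits the single-mediator model — Y on \[1, X, M_j, C\] and M_j on
#' \[1, X, C\] — deliberately omitting the other mediators, and tests the
#' product-of-coefficients statistic alphaX_j betaM_j by the same percentile
#' bootstrap. When other mediators truly act on Y this model is
#' misspecified; that misspecification is exactly what the simulation study
#' quantifies.
#'
#' @inheritParams bootstrap_test_tme
#' @param mediator_index which mediator to test (1..p).
#' @return A `mediation_test_result` with `test = "SME"`.
#' @export
bootstrap_test_sme <- function(data, mediator_index = 1L, B = 1000L,
                               seed = NULL) {
  stopifnot(inherits(data, "mediation_data"), B >= 100L,
            mediator_index >= 1L, mediator_index <= data$p)
  sub <- mediation_data(data$Y, data$X,
                        data$M[, mediator_index, drop = FALSE],
                        if (data$q > 0) data$C else NULL)
  if (!is.null(seed)) set.seed(seed)
  est <- tme(fit_mediation(sub))
  st <- .boot_stats(sub, B, include_sme = FALSE)
  res <- .new_test_result("SME", est, .percentile_p(st$Delta), NULL, B, seed,
                          st$redraws)
  res$mediator_index <- mediator_index
  res
}

#' Single-mediator tests over all mediators ("at least one" rule)
#'
#' Runs [bootstrap_test_sme()] for each mediator. With `correction = "none"`
#' the combined p-value is `min_j p_j`, so comparing it to the significance
#' level implements the rule that rejection of any single-mediator test
#' rejects overall; with `correction = "bonferroni"` the combined p-value is
#' `min(1, p min_j p_j)`.
#'
#' @inheritParams bootstrap_test_tme
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @return A `mediation_test_result` with `test = "SME"`, `component_p` the
#'   per-mediator p-values, `estimate` the per-mediator product statistics.
#' @export
sme_any <- function(data, B = 1000L, seed = NULL,
                    correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(inherits(data, "mediation_data"))
  seeds <- if (is.null(seed)) rep(list(NULL), data$p)
           else as.list((seed + 104729 * seq_len(data$p)) %% .Machine$integer.max)
  runs <- lapply(seq_len(data$p), function(j)
    bootstrap_test_sme(data, j, B = B, seed = seeds[[j]]))
  comp_p <- vapply(runs, `[[`, numeric(1), "p_value")
  est <- vapply(runs, `[[`, numeric(1), "estimate")
  p_comb <- if (correction == "none") min(comp_p)
            else min(1, data$p * min(comp_p))
  res <- .new_test_result("SME", est, p_comb, comp_p, B, seed,
                          sum(vapply(runs, `[[`, integer(1), "redraws")))
  res$correction <- correction
  res
}

#' Run all three mediation tests on one candidate trio
#'
#' Assembles complete-case data for a trio — samples present in all inputs
#' with a non-missing dosage — optionally applies the rank-based inverse
#' normal transform to the trans-gene and each mediator, and runs the TME,
#' CME, and SME ("at least one") bootstrap tests.
#'
#' @param trio one row of the data frame returned by [build_trios()] (or a
#'   list with `snp_id`, `trans_probe_id`, `mediators` semicolon-joined).
#' @param g a [genotype_matrix()].
#' @param e an [expression_matrix()].
#' @param C optional [covariate_table()].
#' @param B bootstrap resamples per test.
#' @param seed optional integer seed; sub-seeds for the three tests are
#'   derived deterministically from it.
#' @param transform `"none"` or `"int"` (inverse normal transform).
#' @return One-row data frame: trio identity, n, `Delta`, semicolon-joined
#'   `delta`, `p_TME`, `p_CME`, semicolon-joined CME `component_p`,
#'   `p_SME_min`, `B`, `seed`; or `NULL` (with a message) when the SNP is
#'   monomorphic on the complete cases.
#' @export
analyze_trio <- function(trio, g, e, C = NULL, B = 1000L, seed = NULL,
                         transform = c("none", "int")) {
  transform <- match.arg(transform)
  snp <- trio$snp_id
  mediators <- strsplit(trio$mediators, ";", fixed = TRUE)[[1L]]
  trans_probe <- trio$trans_probe_id
  if (trans_probe %in% mediators)
    stop("trans probe '", trans_probe, "' cannot also be a mediator")
  si <- match(snp, g$snp_ids)
  if (is.na(si)) stop("SNP '", snp, "' not found in genotypes")
  pi <- match(c(mediators, trans_probe), e$probe_ids)
  if (anyNA(pi))
    stop("probe(s) not found in expression matrix: ",
         paste(c(mediators, trans_probe)[is.na(pi)], collapse = ", "))

  samples <- intersect(g$sample_ids, e$sample_ids)
  if (!is.null(C)) samples <- intersect(samples, C$sample_ids)
  x <- g$dosages[si, match(samples, g$sample_ids)]
  ok <- !is.na(x)
  samples <- samples[ok]; x <- x[ok]
  if (length(unique(x)) < 2L) {
    message("analyze_trio: skipping trio (", snp, ", ", trans_probe,
            "): monomorphic dosage after complete-case assembly")
    return(NULL)
  }
  eidx <- match(samples, e$sample_ids)
  M <- t(e$values[pi[seq_along(mediators)], eidx, drop = FALSE])
  colnames(M) <- mediators
  Y <- e$values[pi[length(pi)], eidx]
  if (transform == "int") {
    Y <- inverse_normal_transform(Y)
    M <- apply(M, 2L, inverse_normal_transform)
  }
  Cm <- if (is.null(C)) NULL else C$values[match(samples, C$sample_ids), , drop = FALSE]
  dat <- mediation_data(Y, x, M, Cm)

  seeds <- if (is.null(seed)) list(NULL, NULL, NULL)
           else as.list((seed + 15485863 * 1:3) %% .Machine$integer.max)
  r_tme <- bootstrap_test_tme(dat, B = B, seed = seeds[[1L]])
  r_cme <- bootstrap_test_cme(dat, B = B, seed = seeds[[2L]])
  r_sme <- sme_any(dat, B = B, seed = seeds[[3L]])

  data.frame(
    snp_id = snp, mediators = paste(mediators, collapse = ";"),
    trans_probe_id = trans_probe, n = dat$n,
    Delta = r_tme$estimate,
    delta = paste(format(r_cme$estimate, digits = 15, trim = TRUE), collapse = ";"),
    p_TME = r_tme$p_value, p_CME = r_cme$p_value,
    p_CME_components = paste(format(r_cme$component_p, digits = 15, trim = TRUE),
                             collapse = ";"),
    p_SME_min = r_sme$p_value,
    p_SME_components = paste(format(r_sme$component_p, digits = 15, trim = TRUE),
                             collapse = ";"),
    B = B, seed = if (is.null(seed)) NA_integer_ else seed,
    stringsAsFactors = FALSE)
}

#' Mediation tests for every trio in a table
#'
#' Convenience driver over [analyze_trio()]; trios whose SNP is monomorphic
#' on the assembled samples are skipped. Per-trio seeds are derived
#' deterministically from `seed` so trios are independent but reproducible.
#'
#' @param trios data frame from [build_trios()].
#' @inheritParams analyze_trio
#' @return Data frame with one row per analyzed trio.
#' @export
mediate_trios <- function(trios, g, e, C = NULL, B = 1000L, seed = NULL,
                          transform = c("none", "int")) {
  transform <- match.arg(transform)
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    s <- if (is.null(seed)) NULL else (seed + 6700417 * i) %% .Machine$integer.max
    analyze_trio(trios[i, ], g, e, C, B = B, seed = s, transform = transform)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
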