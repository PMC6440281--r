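# Joint multi-mediator model fitting and the bootstrap TME/CME/SME tests.

test_that("fit_mediation matches the least-squares oracle on random draws", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(15:40, 1)
    p <- sample(1:3, 1)
    q <- sample(0:2, 1)
    X <- rbinom(n, 2, 0.4)
    if (var(X) == 0) next
    C <- if (q > 0) matrix(rnorm(n * q), n) else NULL
    M <- 0.5 + outer(X, runif(p, -1, 1)) + matrix(rnorm(n * p), n)
    Y <- 0.5 + 0.3 * X + drop(M %*% runif(p, -1, 1)) + rnorm(n)
    f <- fit_mediation(mediation_data(Y, X, M, C))
    lm_out <- if (q > 0) coef(lm(Y ~ X + M + C)) else coef(lm(Y ~ X + M))
    expect_equal(f$beta0, unname(lm_out[1]), tolerance = 1e-10)
    expect_equal(f$betaX, unname(lm_out[2]), tolerance = 1e-10)
    expect_equal(f$betaM, unname(lm_out[3:(2 + p)]), tolerance = 1e-10)
    for (j in seq_len(p)) {
      lmj <- if (q > 0) lm(M[, j] ~ X + C) else lm(M[, j] ~ X)
      expect_equal(f$alphaX[j], unname(coef(lmj)[2]), tolerance = 1e-10)
      expect_equal(f$alpha0[j], unname(coef(lmj)[1]), tolerance = 1e-10)
    }
    # residual-orthogonality invariant of each stage, and Delta = sum(delta)
    expect_equal(tme(f), sum(cme(f)))
    expect_true(isSymmetric(f$Sigma))
    expect_true(all(eigen(f$Sigma, only.values = TRUE)$values > -1e-10))
  }
})

test_that("outcome-noiseless data recover the outcome coefficients exactly", {
  set.seed(102)
  X <- rbinom(40, 2, 0.4)
  M <- cbind(0.5 + 1.0 * X + rnorm(40), 0.5 + 2.0 * X + rnorm(40))
  Y <- 0.5 + 0.3 * X + drop(M %*% c(1, 1))        # no outcome noise
  f <- fit_mediation(mediation_data(Y, X, M))
  expect_equal(f$betaM, c(1, 1), tolerance = 1e-9)
  expect_equal(f$betaX, 0.3, tolerance = 1e-9)
  expect_equal(f$sigma2, 0, tolerance = 1e-12)
})

test_that("collinear mediators are reported as a rank-deficiency error", {
  X <- rep(0:2, each = 5)
  M <- cbind(M1 = X, M2 = 2 * X)     # deterministic in X: unidentifiable
  expect_error(fit_mediation(mediation_data(X + 1, X, M)), "rank deficient")
})

test_that("TME and CME estimands follow the product-of-coefficients rule", {
  f <- structure(list(alphaX = c(1, 2), betaM = c(1, 1)),
                 class = "mediation_fit")
  expect_equal(tme(f), 3)
  expect_equal(cme(f), c(1, 2))
  # cancellation configuration: total effect zero, components nonzero
  f2 <- structure(list(alphaX = c(0.6, 0.6), betaM = c(0.1, -0.1)),
                  class = "mediation_fit")
  expect_equal(tme(f2), 0)
  expect_equal(cme(f2), c(0.06, -0.06))
})

test_that("bootstrap p-values respect their formula bounds and reproduce", {
  set.seed(111)
  dat <- draw_mediation_data(n = 60, betaM = c(0.1, 0.1))
  for (B in c(100, 250)) {
    r <- bootstrap_test_tme(dat, B = B, seed = 5)
    expect_gte(r$p_value, 1 / (B + 1))
    expect_lte(r$p_value, 1)
    r2 <- bootstrap_test_tme(dat, B = B, seed = 5)
    expect_identical(r$p_value, r2$p_value)
  }
  rc <- bootstrap_test_cme(dat, B = 200, seed = 9)
  expect_length(rc$component_p, 2)
  expect_true(all(rc$component_p >= 1 / 201 & rc$component_p <= 1))
  expect_equal(rc$p_value, min(1, 2 * min(rc$component_p)))
})

test_that("with one mediator the TME, CME and SME tests coincide", {
  set.seed(112)
  X <- rbinom(80, 2, 0.3)
  M <- matrix(0.5 + 0.6 * X + rnorm(80), ncol = 1)
  Y <- 0.5 + 0.3 * X + 0.3 * M[, 1] + rnorm(80)
  dat <- mediation_data(Y, X, M)
  r_t <- bootstrap_test_tme(dat, B = 300, seed = 4)
  r_c <- bootstrap_test_cme(dat, B = 300, seed = 4)
  r_s <- bootstrap_test_sme(dat, 1, B = 300, seed = 4)
  expect_equal(r_t$estimate, r_c$estimate[1])
  expect_equal(r_t$estimate, r_s$estimate)
  expect_identical(r_t$p_value, r_c$p_value)
  expect_identical(r_t$p_value, r_s$p_value)
})

test_that("compiled bootstrap statistics agree with the R fit on the identity resample", {
  set.seed(113)
  dat <- draw_mediation_data(n = 50, betaM = c(0.2, -0.1))
  idx <- matrix(rep(seq_len(dat$n), 2), ncol = 2)    # identity twice
  st <- medtrans:::boot_mediation_stats(dat$Y, dat$X, dat$M, dat$C, idx, TRUE)
  f <- fit_mediation(dat)
  expect_equal(st$delta[1, ], cme(f), tolerance = 1e-10)
  expect_equal(st$Delta[1], tme(f), tolerance = 1e-10)
  f1 <- fit_mediation(mediation_data(dat$Y, dat$X, dat$M[, 1, drop = FALSE]))
  f2 <- fit_mediation(mediation_data(dat$Y, dat$X, dat$M[, 2, drop = FALSE]))
  expect_equal(st$sme[1, ], c(tme(f1), tme(f2)), tolerance = 1e-10)
})

test_that("sme_any applies the at-least-one and Bonferroni rules", {
  set.seed(114)
  dat <- draw_mediation_data(n = 80, alphaX = c(0.8, 0.8), betaM = c(0.4, 0))
  r_none <- sme_any(dat, B = 200, seed = 3)
  expect_equal(r_none$p_value, min(r_none$component_p))
  r_bonf <- sme_any(dat, B = 200, seed = 3, correction = "bonferroni")
  expect_equal(r_bonf$p_value, min(1, 2 * min(r_bonf$component_p)))
  # single mediator: identical to bootstrap_test_sme
  dat1 <- mediation_data(dat$Y, dat$X, dat$M[, 1, drop = FALSE])
  s1 <- sme_any(dat1, B = 200, seed = 10)
  expect_length(s1$component_p, 1)
  expect_equal(s1$p_value, s1$component_p[1])
})

test_that("analyze_trio assembles complete cases and respects preconditions", {
  spec <- fixture_spec(n_samples = 200, n_snps = 2,
                       planted_trios = list(planted_trio(1, 2)),
                       n_null_probes = 2, seed = 7, missing_rate = 0.02)
  g <- generate_genotype_matrix(spec)
  e <- generate_expression(spec, g)
  trio <- data.frame(snp_id = "snp001", mediators = "med1_1;med1_2",
                     trans_probe_id = "trans1", stringsAsFactors = FALSE)
  res <- analyze_trio(trio, g, e, B = 300, seed = 2)
  expect_equal(res$n, sum(!is.na(g$dosages["snp001", ])))
  expect_lt(res$p_TME, 0.05)

  # renaming samples (same order) leaves every number identical
  g2 <- g; g2$sample_ids <- paste0("x", g$sample_ids)
  colnames(g2$dosages) <- g2$sample_ids
  e2 <- e; e2$sample_ids <- paste0("x", e$sample_ids)
  colnames(e2$values) <- e2$sample_ids
  res2 <- analyze_trio(trio, g2, e2, B = 300, seed = 2)
  expect_equal(res2[, -1] , res[, -1])

  # trans probe duplicated among mediators is a precondition violation
  bad <- trio; bad$mediators <- "med1_1;trans1"
  expect_error(analyze_trio(bad, g, e), "cannot also be a mediator")

  # monomorphic SNP is skipped with a message, not an error
  g3 <- g; g3$dosages["snp002", ] <- 0
  trio3 <- data.frame(snp_id = "snp002", mediators = "med1_1",
                      trans_probe_id = "trans1", stringsAsFactors = FALSE)
  expect_message(out <- analyze_trio(trio3, g3, e, B = 300), "monomorphic")
  expect_null(out)

  # inverse-normal transform option runs and changes the estimate scale
  res_int <- analyze_trio(trio, g, e, B = 300, seed = 2, transform = "int")
  expect_false(identical(res_int$Delta, res$Delta))
})
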