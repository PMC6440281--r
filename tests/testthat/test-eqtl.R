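# cis/trans classification, association testing, FDR and trio construction.

test_that("classify_pair anchors distance to the probe interval", {
  expect_identical(classify_pair("chr1", 500000, "chr1", 1200000, 1201000), "cis")
  expect_identical(classify_pair("chr1", 100, "chr2", 100, 200), "trans")
  # boundary: exactly window + 1 away is trans, exactly window is cis
  expect_identical(classify_pair("chr1", 100, "chr1", 1000101, 1000200), "trans")
  expect_identical(classify_pair("chr1", 100, "chr1", 1000100, 1000200), "cis")
  # SNP inside the interval: distance 0
  expect_identical(classify_pair("chr1", 150, "chr1", 100, 200), "cis")
  # orientation-free: swapped start/end classify identically
  expect_identical(classify_pair("chr1", 500, "chr1", 900, 300),
                   classify_pair("chr1", 500, "chr1", 300, 900))
})

test_that("association_test matches the normal-equations oracle", {
  set.seed(71)
  for (i in 1:100) {
    n <- sample(15:40, 1)
    k <- sample(0:3, 1)
    x <- rbinom(n, 2, runif(1, 0.2, 0.5))
    if (var(x) == 0) next
    C <- if (k > 0) matrix(rnorm(n * k), n) else NULL
    y <- 0.2 * x + rnorm(n)
    got <- association_test(y, x, C)
    want <- ols_oracle(y, x, C)
    expect_equal(got$effect, want$effect, tolerance = 1e-10)
    expect_equal(got$stderr, want$stderr, tolerance = 1e-10)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("association_test handles missing dosages, degenerate fits, errors", {
  set.seed(72)
  x <- rbinom(30, 2, 0.4); x[c(2, 9)] <- NA
  y <- rnorm(30)
  got <- association_test(y, x)
  ok <- !is.na(x)
  want <- ols_oracle(y[ok], x[ok])
  expect_equal(got$effect, want$effect, tolerance = 1e-12)
  expect_equal(got$n, sum(ok))

  # exact fit: effect recovered, p floored, flagged
  x2 <- c(0, 0, 1, 1, 2, 2)
  got2 <- association_test(2 * x2 + 1, x2)
  expect_equal(got2$effect, 2)
  expect_true(got2$degenerate)
  expect_equal(got2$p, .Machine$double.eps)

  expect_error(association_test(rnorm(6), rep(1, 6)), "constant")

  # covariate orthogonal to x and y leaves the effect unchanged
  set.seed(73)
  x3 <- rep(0:2, each = 8); y3 <- 0.5 * x3 + rnorm(24)
  C3 <- matrix(rnorm(24), 24)
  C3 <- residuals(lm(C3 ~ x3 + y3))      # orthogonalize
  a0 <- association_test(y3, x3)
  a1 <- association_test(y3, x3, C3)
  expect_equal(a1$effect, a0$effect, tolerance = 1e-10)
  expect_equal(a1$df, a0$df - 1L)
})

test_that("bh_fdr reproduces the step-up procedure", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 0)), "0, 1")
  set.seed(81)
  for (i in 1:30) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    alpha <- runif(1, 0.01, 0.3)
    expect_identical(bh_fdr(p) <= alpha, bh_reject_oracle(p, alpha))
    expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-15))
  }
})

test_that("eqtl_scan counts pairs per mode and finds planted associations", {
  set.seed(91)
  n <- 300
  x <- rbinom(n, 2, 0.4)
  g <- toy_genotypes(matrix(x, nrow = 1), chrom = "chr1", pos = 5e6L)
  vals <- rbind(0.8 * x + rnorm(n),   # cis probe (within 1 Mb)
                rnorm(n))             # trans probe (other chromosome)
  e <- expression_matrix(vals, chrom = c("chr1", "chr2"),
                         start = c(5.4e6, 5.4e6), end = c(5.401e6, 5.401e6),
                         probe_ids = c("pc", "pt"),
                         sample_ids = paste0("ind", 1:n))
  expect_equal(nrow(eqtl_scan(g, e, mode = "cis")), 1L)
  expect_equal(nrow(eqtl_scan(g, e, mode = "trans")), 1L)
  both <- eqtl_scan(g, e, mode = "both")
  expect_equal(nrow(both), 2L)
  expect_lt(both$p[both$probe_id == "pc"], 1e-6)

  # zero overlapping samples is an error
  e2 <- e; e2$sample_ids <- paste0("other", 1:n)
  colnames(e2$values) <- e2$sample_ids
  expect_error(eqtl_scan(g, e2), "overlap")
})

test_that("null scans are calibrated and covariate-adjusted scans match lm", {
  set.seed(92)
  n <- 60
  g <- toy_genotypes(matrix(rbinom(n * 20, 2, 0.3), nrow = 20),
                     chrom = rep(c("chr1", "chr2"), 10),
                     pos = as.integer(rep(seq(1e6, 3.7e7, by = 4e6), 2)[1:20]))
  e <- expression_matrix(matrix(rnorm(40 * n), nrow = 40),
                         chrom = rep(c("chr1", "chr2"), each = 20),
                         start = rep(seq(2e6, 7.8e7, by = 4e6), 2)[1:40],
                         end = rep(seq(2e6, 7.8e7, by = 4e6), 2)[1:40] + 1000,
                         probe_ids = paste0("p", 1:40),
                         sample_ids = paste0("ind", 1:n))
  cv <- covariate_table(matrix(rnorm(n * 2), n,
                               dimnames = list(paste0("ind", 1:n), c("pc1", "sex"))))
  rec <- eqtl_scan(g, e, cv, mode = "both")
  expect_equal(nrow(rec), 20 * 40)
  # no trans p-value anywhere near the trans threshold under the null
  expect_true(all(rec$p[rec$relation == "trans"] > 1e-6))
  # global level: fraction under 0.05 within a generous binomial band
  expect_lt(abs(mean(rec$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / nrow(rec)))
  # spot-check one record against lm with covariates
  r1 <- rec[rec$snp_id == "s3" & rec$probe_id == "p17", ]
  fit <- summary(lm(e$values["p17", ] ~ g$dosages["s3", ] + cv$values))
  expect_equal(r1$effect, fit$coefficients[2, 1], tolerance = 1e-10)
  expect_equal(r1$p, fit$coefficients[2, 4], tolerance = 1e-10)
  # q-values computed within relation class
  for (cl in c("cis", "trans")) {
    sel <- rec$relation == cl
    expect_equal(rec$q[sel], bh_fdr(rec$p[sel]))
  }
})

test_that("build_trios applies the selection thresholds strictly", {
  mk <- function(snp, probe, rel, p, q) data.frame(
    snp_id = snp, probe_id = probe, relation = rel, effect = 1, stderr = 1,
    t_stat = 1, p = p, q = q, n = 100, degenerate = FALSE,
    stringsAsFactors = FALSE)
  cis <- rbind(mk("rs1", "g1", "cis", 1e-8, 0.01),
               mk("rs1", "g2", "cis", 1e-7, 0.01),
               mk("rs2", "g3", "cis", 1e-9, 0.01))
  trans <- rbind(mk("rs1", "t1", "trans", 1e-7, 0.2),
                 mk("rs2", "t2", "trans", 1e-5, 0.2),   # fails strict 1e-6
                 mk("rs3", "t3", "trans", 1e-9, 0.2))   # no cis mediators
  tr <- build_trios(trans, cis)
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$snp_id, "rs1")
  expect_equal(tr$n_mediators, 2L)
  expect_identical(tr$mediators, "g1;g2")   # ascending cis p

  # trans p exactly 1e-6 is excluded ("less than" is strict)
  tr2 <- build_trios(mk("rs1", "t1", "trans", 1e-6, 0.2), cis)
  expect_equal(nrow(tr2), 0L)

  # >5 qualifying cis genes are truncated to the 5 smallest p
  cis7 <- do.call(rbind, lapply(1:7, function(i)
    mk("rs9", paste0("c", i), "cis", i * 1e-8, 0.01)))
  tr3 <- build_trios(mk("rs9", "t9", "trans", 1e-8, 0.2), cis7)
  expect_equal(tr3$n_mediators, 5L)
  expect_identical(tr3$mediators, "c1;c2;c3;c4;c5")

  # cis genes above the FDR threshold do not qualify
  cis_bad <- mk("rs1", "g1", "cis", 1e-3, 0.2)
  expect_equal(nrow(build_trios(mk("rs1", "t1", "trans", 1e-8, .2), cis_bad)), 0L)
})
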