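# Synthetic-fixture generators: reproducibility, marginal statistics, and
# file-bundle round trips.

test_that("genotype fixtures are seed-reproducible with HWE-consistent draws", {
  spec <- fixture_spec(n_samples = 500, n_snps = 40, seed = 13)
  g1 <- generate_genotype_matrix(spec)
  g2 <- generate_genotype_matrix(spec)
  expect_identical(g1$dosages, g2$dosages)
  # empirical MAF close to the drawn MAF (binomial tolerance at n = 500)
  true_maf <- attr(g1, "true_maf")
  emp_f <- rowMeans(g1$dosages) / 2
  emp <- pmin(emp_f, 1 - emp_f)
  se <- sqrt(true_maf * (1 - true_maf) / (2 * 500))
  expect_true(all(abs(emp_f - true_maf) < 4 * se))
  expect_true(all(emp <= 0.5))
  # two-chromosome layout
  expect_setequal(unique(g1$chrom), c("chr1", "chr2"))
})

test_that("HWE p-values on generated SNPs are approximately uniform", {
  spec <- fixture_spec(n_samples = 200, n_snps = 400, seed = 19)
  g <- generate_genotype_matrix(spec)
  p <- apply(g$dosages, 1, function(d) {
    cnt <- genotype_counts(d)
    hwe_exact_test(cnt["n0"], cnt["n1"], cnt["n2"])
  })
  # discrete exact p-values are conservative; one-sided binomial band
  expect_lte(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
})

test_that("planted trios are visible to the scan and null probes are quiet", {
  spec <- fixture_spec(n_samples = 300, n_snps = 4,
                       planted_trios = list(planted_trio(1, 2)),
                       n_null_probes = 20, seed = 23)
  g <- generate_genotype_matrix(spec)
  e <- generate_expression(spec, g)
  # mediators are cis to their SNP, the trans probe is on the other chromosome
  med_rows <- grep("^med1_", e$probe_ids)
  expect_true(all(classify_pair(g$chrom[1], g$pos[1], e$chrom[med_rows],
                                e$start[med_rows], e$end[med_rows]) == "cis"))
  tr_row <- match("trans1", e$probe_ids)
  expect_false(e$chrom[tr_row] == g$chrom[1])

  rec <- eqtl_scan(g, e, mode = "both")
  planted_cis <- rec[rec$snp_id == "snp001" & rec$probe_id %in% c("med1_1", "med1_2"), ]
  expect_true(all(planted_cis$q < 0.05))
  planted_trans <- rec[rec$snp_id == "snp001" & rec$probe_id == "trans1", ]
  expect_lt(planted_trans$p, 1e-6)
  # null probes: cis p-values roughly uniform
  null_cis <- rec[grepl("^null", rec$probe_id) & rec$relation == "cis", ]
  if (nrow(null_cis) > 10)
    expect_lte(mean(null_cis$p < 0.05),
               0.05 + 3 * sqrt(0.05 * 0.95 / nrow(null_cis)))
})

test_that("annotation panels reproduce their marginal rates", {
  pan <- generate_annotation_panel(100000, trait_fraction = 0.014, seed = 29)
  expect_equal(mean(pan$trait_associated), 0.014,
               tolerance = 4 * sqrt(0.014 * 0.986 / 1e5) / 0.014)
  pan0 <- generate_annotation_panel(500, trait_fraction = 0,
                                    cis_count_distribution = 1, seed = 31)
  expect_true(all(pan0$n_cis_genes == 0))
  expect_identical(generate_annotation_panel(100, seed = 5),
                   generate_annotation_panel(100, seed = 5))
})

test_that("fixture bundles round-trip through the readers", {
  spec <- fixture_spec(n_samples = 60, n_snps = 4, missing_rate = 0.03,
                       planted_trios = list(planted_trio(2, 2)),
                       n_null_probes = 3, seed = 37)
  dir <- withr::local_tempdir()
  paths <- write_fixture_bundle(spec, dir)
  expect_true(all(file.exists(paths)))
  g <- generate_genotype_matrix(spec)
  e <- generate_expression(spec, g)
  expect_identical(read_genotypes(paths["genotypes"])$dosages, g$dosages)
  expect_equal(read_expression(paths["expression"])$values, e$values,
               tolerance = 1e-12)
  cv <- read_covariates(paths["covariates"])
  expect_identical(cv$covariate_names, "sex")
  expect_true(all(cv$values %in% 0:1))
  # manifest records the seed for byte-identical regeneration
  expect_true(any(grepl("seed: 37", readLines(paths["manifest"]))))
  dir2 <- withr::local_tempdir()
  paths2 <- write_fixture_bundle(spec, dir2)
  expect_identical(readLines(paths["genotypes"]), readLines(paths2["genotypes"]))
  expect_identical(readLines(paths["expression"]), readLines(paths2["expression"]))
})
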