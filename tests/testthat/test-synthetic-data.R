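test_that("configuration invariants are enforced", {
  expect_error(cohort_config(phenotype_proportions = c(0.5, 0.4, 0.2)), "simplex")
  expect_error(cohort_config(infiltration_levels = c(0.3, 0.2, 0.6)), "increasing")
  expect_error(cohort_config(n_genes = 10, n_cell_types = 5, markers_per_type = 10),
               "exceed")
  expect_error(cohort_config(noise_sd = -1), "noise_sd")
  expect_error(cohort_config(vaf_beta_params = c(1, -1)), "positive")
})

test_that("noiseless mixtures reproduce the generative formula entrywise", {
  cfg <- cohort_config(n_genes = 120, n_samples = 25, noise_sd = 0, seed = 5)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  m <- as.matrix(co$expression[-1])
  rownames(m) <- co$expression$gene
  recon <- outer(tr$tumor_profile, tr$purity) +
    tr$cell_profiles %*% sweep(tr$fractions, 2, 1 - tr$purity, "*")
  expect_equal(unname(m), unname(recon), tolerance = 1e-12)

  # fraction columns on the simplex; purity + non-tumor fraction = 1
  expect_equal(unname(colSums(tr$fractions)), rep(1, 25), tolerance = 1e-9)
  expect_true(all(tr$purity >= 0 & tr$purity <= 1))
})

test_that("pure tumor at zero noise collapses every column to the tumor profile", {
  cfg <- cohort_config(n_genes = 60, n_samples = 8, noise_sd = 0,
                       markers_per_type = 5,
                       infiltration_levels = c(1e-9, 2e-9, 3e-9), seed = 2)
  co <- simulate_cohort(cfg)
  m <- as.matrix(co$expression[-1])
  for (j in seq_len(ncol(m))) {
    expect_equal(unname(m[, j]), unname(co$truth$tumor_profile), tolerance = 1e-6)
  }
})

test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_genes = 100, n_samples = 20, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$fractions, b$truth$fractions)
})

test_that("marker-set mean expression rises with planted infiltration level", {
  co <- simulate_cohort(cohort_config(n_genes = 400, n_samples = 150, seed = 4))
  sets <- simulate_gene_sets(co$truth)
  m <- as.matrix(co$expression[-1])
  rownames(m) <- co$expression$gene
  pheno <- co$truth$phenotype[colnames(m)]
  means <- tapply(colMeans(m[sets$immune, ]), pheno, mean)
  expect_lt(means[["immune-L"]], means[["immune-M"]])
  expect_lt(means[["immune-M"]], means[["immune-H"]])
})

test_that("gene sets cover planted types, stay disjoint, mark their own profile", {
  cfg <- cohort_config(n_genes = 600, n_samples = 10, n_cell_types = 22,
                       markers_per_type = 10, seed = 3)
  co <- simulate_cohort(cfg)
  sets <- simulate_gene_sets(co$truth)
  expect_length(sets, 24L)  # 22 marker sets + stromal + immune
  per_type <- sets[seq_len(22)]
  expect_equal(anyDuplicated(unlist(per_type)), 0L)
  expect_true(all(unlist(sets) %in% co$expression$gene))
  # each marker set most expressed in its own cell-type profile
  prof <- co$truth$cell_profiles
  for (ct in names(per_type)) {
    own <- mean(prof[per_type[[ct]], ct])
    others <- mean(prof[per_type[[ct]], setdiff(colnames(prof), ct)])
    expect_gt(own, others)
  }
})

test_that("simulated VAFs match the Beta mean and degenerate cleanly", {
  maf <- simulate_maf(sprintf("P%03d", 1:100), mutations_per_sample = 100,
                      vaf_beta_params = c(2, 5), seed = 8)
  v <- maf_vaf(maf)$vaf
  expect_gt(length(v), 9000)
  beta_mean <- 2 / 7
  beta_se <- sqrt(2 * 5 / ((2 + 5)^2 * (2 + 5 + 1))) / sqrt(length(v))
  expect_lt(abs(mean(v) - beta_mean), 3 * beta_se + 0.005)  # 0.005 = depth rounding

  # near-degenerate Beta concentrates all VAFs at 0.3 -> MATH 0
  deg <- simulate_maf(c("P1"), mutations_per_sample = 50,
                      vaf_beta_params = c(3e5, 7e5), seed = 1)
  expect_true(all(maf_vaf(deg)$vaf == 0.3))
  expect_equal(math_by_sample(deg)$math, 0)

  expect_identical(simulate_maf(c("A", "B"), seed = 9),
                   simulate_maf(c("A", "B"), seed = 9))
})

test_that("cell-line truth reproduces IC50 exactly when noiseless", {
  tr <- simulate_cellline_training(n_lines = 40, n_genes = 50,
                                   n_effect_genes = 5, noise_sd = 0, seed = 3)
  x <- as.matrix(tr$expression[-1])
  rownames(x) <- tr$expression$gene
  b <- tr$truth$coefficients
  y_hat <- tr$truth$intercept + as.numeric(crossprod(x[names(b), ], b))
  expect_equal(tr$ic50$log_ic50, y_hat, tolerance = 1e-12)

  flat <- simulate_cellline_training(n_lines = 20, n_genes = 30,
                                     n_effect_genes = 1, effect_sd = 0,
                                     noise_sd = 0, seed = 4)
  expect_equal(flat$ic50$log_ic50, rep(flat$truth$intercept, 20))

  expect_error(simulate_cellline_training(n_genes = 5, n_effect_genes = 6),
               "n_effect_genes")
})

test_that("survival times carry the planted hazard ordering", {
  co <- simulate_cohort(cohort_config(n_samples = 600, seed = 21))
  med <- tapply(co$clinical$time, co$clinical$phenotype, median)
  expect_gt(med[["immune-L"]], med[["immune-M"]])
  expect_gt(med[["immune-M"]], med[["immune-H"]])
  expect_true(all(co$clinical$event %in% 0:1))
  expect_gt(sum(co$clinical$event), 0)
  expect_gt(sum(co$clinical$event == 0), 0)
})
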