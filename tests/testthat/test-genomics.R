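maf_fixture <- function() {
  tibble::tibble(
    sample = c(rep("P1", 3), rep("P2", 2)),
    gene = c("TP53", "EGFR", "IDH1", "TP53", "ATRX"),
    chromosome = c("17", "7", "2", "17", "X"),
    position = c(100L, 200L, 300L, 100L, 400L),
    variant_classification = c("Missense_Mutation", "Missense_Mutation",
                               "Missense_Mutation", "Nonsense_Mutation", "Silent"),
    ref_count = c(70L, 50L, 80L, 60L, 90L),
    alt_count = c(30L, 50L, 20L, 40L, 10L)
  )
}

test_that("TMB is the count/capture ratio, linear, zero-filled", {
  maf38 <- tibble::tibble(sample = rep("P1", 38), gene = "G",
                          chromosome = "1", position = 1:38,
                          variant_classification = "Missense_Mutation",
                          ref_count = 50L, alt_count = 50L)
  tmb <- compute_tmb(maf38, capture_size_mb = 38)
  expect_equal(tmb$tmb, 1.0)
  expect_equal(tmb$log2_tmb, 0)

  # doubling the records doubles TMB exactly
  tmb2 <- compute_tmb(dplyr::bind_rows(maf38, dplyr::mutate(maf38, position = position + 100L)),
                      capture_size_mb = 38)
  expect_equal(tmb2$tmb, 2 * tmb$tmb)

  # absent samples get zero; log2 of zero burden is missing at pseudocount 0
  t0 <- compute_tmb(maf_fixture(), samples = c("P1", "P2", "P3"))
  expect_equal(t0$mutation_count[t0$sample == "P3"], 0L)
  expect_true(is.na(t0$log2_tmb[t0$sample == "P3"]))
  expect_equal(t0$tmb[t0$sample == "P1"], 3 / 38)

  # empty table with a sample universe -> all zeros
  te <- compute_tmb(maf_fixture()[0, ], samples = c("A", "B"))
  expect_equal(te$tmb, c(0, 0))

  # classification include-list restricts the count
  tf <- compute_tmb(maf_fixture(), classifications = "Missense_Mutation")
  expect_equal(tf$mutation_count[tf$sample == "P1"], 3L)
  expect_equal(tf$mutation_count[tf$sample == "P2"], 0L)

  expect_error(compute_tmb(maf_fixture(), capture_size_mb = 0), "> 0")
})

test_that("MATH matches the hand-evaluated MAD/median form", {
  # med 0.25, MAD 1.4826 * 0.05 -> 100 * 0.074130 / 0.25
  expect_equal(math_score(c(0.2, 0.25, 0.3)), 29.652)
  expect_equal(math_score(c(0.4, 0.4, 0.4)), 0)
  # scale invariance of the MAD/median ratio
  v <- c(0.1, 0.18, 0.22, 0.35)
  expect_equal(math_score(v), math_score(v * 2))
  expect_equal(math_score(v), math_score(v * 0.5))
  # mean-preserving spread increases the score
  expect_gt(math_score(c(0.15, 0.25, 0.35)), math_score(c(0.2, 0.25, 0.3)))
  expect_error(math_score(0.3), "at least 2")
  expect_error(math_score(c(0.2, 1.5)), "\\(0, 1\\]")
})

test_that("per-sample MATH uses only VAF-bearing records", {
  maf <- maf_fixture()
  out <- math_by_sample(maf)
  p1 <- maf_vaf(maf[maf$sample == "P1", ])$vaf
  expect_equal(out$math[out$sample == "P1"], math_score(p1))
  # a sample with a single VAF gets NA
  one <- maf[maf$sample == "P2", ][1, ]
  expect_true(is.na(math_by_sample(one)$math))
})

test_that("recurrent sites use a strict threshold on (chrom, position) keys", {
  base <- tibble::tibble(
    sample = sprintf("P%d", 1:6), gene = "X", chromosome = "5",
    position = 1000L, variant_classification = "Missense_Mutation",
    ref_count = 50L, alt_count = 50L)
  hits <- recurrent_site_counts(base, min_n = 5)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$count, 6L)
  expect_equal(recurrent_site_counts(base[1:5, ], min_n = 5)$count, integer(0))

  planted <- simulate_maf(sprintf("P%02d", 1:30), mutations_per_sample = 10,
                          hotspot = list(chromosome = "7", position = 55249071L,
                                         n = 12), seed = 5)
  hits2 <- recurrent_site_counts(planted, min_n = 5)
  expect_true(nrow(hits2) >= 1)
  expect_equal(hits2$position[1], 55249071L)
  expect_equal(hits2$count[1], 12L)
})

test_that("chi-square matches hand values and the textbook formula", {
  expect_equal(chi_square_test(matrix(c(10, 20, 20, 10), 2))$statistic,
               20 / 3, tolerance = 1e-12)
  # proportional rows are exactly independent
  expect_equal(chi_square_test(matrix(c(10, 20, 20, 40), 2))$statistic, 0)
  # fuzz against the independent margin-product formula
  set.seed(13)
  for (i in 1:100) {
    r <- sample(2:4, 1); c <- sample(2:4, 1)
    m <- matrix(rpois(r * c, 20) + 1, r)
    got <- chi_square_test(m)
    expect_lt(abs(got$statistic - textbook_chisq(m)), 1e-9)
    expect_equal(got$df, (r - 1L) * (c - 1L))
  }
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "zero row or column")
  expect_error(chi_square_test(matrix(c(0.5, 1, 1, 1), 2)), "integer")
})

test_that("phenotype-by-feature cross-tabulation orders and drops correctly", {
  labels <- tibble::tibble(
    sample = sprintf("s%d", 1:6), cluster_id = c(1L, 1L, 2L, 2L, 3L, 3L),
    phenotype = factor(c("immune-L", "immune-L", "immune-M", "immune-M",
                         "immune-H", "immune-H"),
                       levels = c("immune-L", "immune-M", "immune-H")))
  feat <- tibble::tibble(sample = sprintf("s%d", 1:6),
                         idh = c("MT", "WT", "MT", NA, "WT", "WT"))
  expect_message(tab <- phenotype_feature_table(labels, feat), "1 sample")
  expect_equal(rownames(tab), c("immune-L", "immune-M", "immune-H"))
  expect_equal(colnames(tab), c("MT", "WT"))  # first-seen order
  expect_equal(sum(tab), 5)
  expect_equal(unname(tab["immune-H", ]), c(0, 2))

  # one sample per phenotype, single level
  l3 <- labels[c(1, 3, 5), ]
  f3 <- tibble::tibble(sample = l3$sample, g = "same")
  t3 <- phenotype_feature_table(l3, f3)
  expect_equal(dim(t3), c(3L, 1L))
  expect_equal(unname(t3[, 1]), c(1, 1, 1))

  expect_error(phenotype_feature_table(labels,
    tibble::tibble(sample = "zz", idh = "MT")), "shared")
})
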