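test_that("ridge coefficients equal the closed form on a toy design", {
  # 2 genes, 3 lines, lambda = 1
  x <- matrix(c(1, 2, 3, 2, 1, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("l1", "l2", "l3")))
  y <- c(1, 2, 3)
  mod <- train_ridge_model(expression_matrix(x, unit = "COUNTS"), y,
                           lambda_grid = 1, folds = 3, var_quantile = 0)
  # independent closed form on the standardized design
  z <- t((x - rowMeans(x)) / apply(x, 1, sd))
  beta <- solve(t(z) %*% z + diag(2), t(z) %*% (y - mean(y)))
  expect_equal(unname(mod$coefficients), as.numeric(beta), tolerance = 1e-8)
  expect_equal(mod$intercept, mean(y))

  # shrinkage limit: huge lambda sends coefficients to zero, fits to the mean
  big <- train_ridge_model(expression_matrix(x, unit = "COUNTS"), y,
                           lambda_grid = 1e9 * 3, folds = 3, var_quantile = 0)
  expect_true(all(abs(big$coefficients) < 1e-6))
  pred <- predict_ic50(big, expression_matrix(x, unit = "COUNTS"))
  expect_equal(pred$predicted_log_ic50, rep(mean(y), 3), tolerance = 1e-3)
})

test_that("coefficient norms shrink monotonically in lambda", {
  tr <- simulate_cellline_training(n_lines = 50, n_genes = 30, seed = 2)
  norms <- sapply(c(0.01, 1, 100, 1e4), function(lam) {
    m <- train_ridge_model(tr$expression, tr$ic50, lambda_grid = lam,
                           folds = 5, var_quantile = 0)
    sqrt(sum(m$coefficients^2))
  })
  expect_true(all(diff(norms) < 0))
})

test_that("noiseless generative coefficients are recovered within 5%", {
  tr <- simulate_cellline_training(n_lines = 100, n_genes = 80,
                                   n_effect_genes = 10, noise_sd = 0, seed = 5)
  mod <- train_ridge_model(tr$expression, tr$ic50, lambda_grid = 1e-6,
                           folds = 10, var_quantile = 0)
  raw_scale <- mod$coefficients / mod$scale   # back to raw-expression units
  truth <- tr$truth$coefficients
  expect_lt(max(abs(raw_scale[names(truth)] - truth) / abs(truth)), 0.05)
  # all other genes essentially zero
  rest <- setdiff(names(raw_scale), names(truth))
  expect_lt(max(abs(raw_scale[rest])), max(abs(truth)) * 0.01)
})

test_that("CV lambda selection is deterministic given the seed", {
  tr <- simulate_cellline_training(n_lines = 60, n_genes = 40, seed = 3)
  m1 <- train_ridge_model(tr$expression, tr$ic50, folds = 10, seed = 7)
  m2 <- train_ridge_model(tr$expression, tr$ic50, folds = 10, seed = 7)
  expect_identical(m1$lambda, m2$lambda)
  expect_identical(m1$coefficients, m2$coefficients)
  expect_identical(m1$cv_table, m2$cv_table)
})

test_that("held-out tumors are predicted accurately at moderate noise", {
  tr <- simulate_cellline_training(n_lines = 200, n_genes = 100,
                                   n_effect_genes = 10, noise_sd = 0.1, seed = 6)
  keep <- function(expr, idx) {
    out <- expr[, c(1, 1 + idx)]
    attr(out, "unit") <- "COUNTS"
    class(out) <- class(expr)
    out
  }
  mod <- train_ridge_model(keep(tr$expression, 1:150), tr$ic50[1:150, ],
                           folds = 10, var_quantile = 0)
  pred <- predict_ic50(mod, keep(tr$expression, 151:200))
  expect_gt(cor(pred$predicted_log_ic50, tr$ic50$log_ic50[151:200]), 0.8)

  # a training line predicts exactly at its fitted value
  fit_line <- predict_ic50(mod, keep(tr$expression, 1))
  z <- (as.matrix(tr$expression[-1])[match(mod$genes, tr$expression$gene), 1] -
          mod$center) / mod$scale
  expect_equal(fit_line$predicted_log_ic50,
               mod$intercept + sum(z * mod$coefficients), tolerance = 1e-10)
})

test_that("gene-overlap guards and imputation behave", {
  tr <- simulate_cellline_training(n_lines = 40, n_genes = 30, seed = 8)
  mod <- train_ridge_model(tr$expression, tr$ic50, folds = 5)
  none <- expression_matrix(matrix(1:4, 2, dimnames = list(c("zz1", "zz2"),
                                                           c("t1", "t2"))),
                            unit = "COUNTS")
  expect_error(predict_ic50(mod, none), "model genes present")
  expect_error(train_ridge_model(tr$expression, tr$ic50, folds = 100), "folds")
  expect_error(train_ridge_model(tr$expression, c(NA, tr$ic50$log_ic50[-1])),
               "finite")
})

test_that("response comparisons gate on normality and match an F oracle", {
  labels <- tibble::tibble(
    sample = sprintf("s%d", 1:9),
    phenotype = factor(rep(c("immune-L", "immune-M", "immune-H"), each = 3),
                       levels = c("immune-L", "immune-M", "immune-H")))
  # identical values -> KW statistic 0
  same <- stats::setNames(rep(c(1, 2, 3), 3), labels$sample)
  res0 <- compare_response(same, labels, test = "kruskal-wallis")
  expect_equal(res0$test$statistic, 0)

  # ANOVA F equals the between/within mean-square ratio on a 3x3 table
  y <- c(1, 2, 3, 4, 5, 6, 7, 8, 10)
  preds <- stats::setNames(y, labels$sample)
  res <- compare_response(preds, labels, test = "anova")
  g <- rep(1:3, each = 3)
  gm <- tapply(y, g, mean)
  ssb <- sum(3 * (gm - mean(y))^2); ssw <- sum((y - gm[g])^2)
  expect_equal(res$test$statistic, (ssb / 2) / (ssw / 6), tolerance = 1e-12)
  expect_equal(res$medians$n, rep(3L, 3))

  # planted shift is detected with high power
  signif <- sapply(1:20, function(s) {
    set.seed(3000 + s)
    lab <- tibble::tibble(sample = sprintf("s%d", 1:300),
                          phenotype = factor(rep(c("immune-L", "immune-M", "immune-H"),
                                                 each = 100)))
    v <- rnorm(300)
    v[lab$phenotype == "immune-L"] <- v[lab$phenotype == "immune-L"] - 2
    compare_response(stats::setNames(v, lab$sample), lab,
                     test = "kruskal-wallis")$test$p_value < 0.001
  })
  expect_gte(sum(signif), 19)

  expect_error(compare_response(stats::setNames(1:3, c("a", "b", "c")), labels),
               "shared")
})
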