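#' Train a ridge-regression model for log IC50 from expression
#'
#' Mirrors the cell-line-trained ridge approach used for drug-response
#' transfer: genes in the lowest `var_quantile` of training variance are
#' removed, the rest are standardized by training mean and sd, and ridge
#' coefficients are the closed form `(X'X + lambda I)^-1 X'y` with an
#' unpenalized intercept (the training mean of centred y). The penalty is
#' chosen from `lambda_grid` by 10-fold cross-validated RMSE with a seeded,
#' recorded fold assignment, so selection is deterministic given the seed.
#'
#' @param train_expr Gene-by-line [expression_matrix()] of training
#'   expression.
#' @param ic50 Numeric vector of per-line log IC50 (ordered as the columns of
#'   `train_expr`, or named by line), or a tibble with columns `line`,
#'   `log_ic50`.
#' @param lambda_grid Positive penalty grid; default 25 points log-spaced in
#'   `[1e-3, 1e3]`.
#' @param folds Number of CV folds (must not exceed the number of lines).
#' @param var_quantile Variance-quantile below which genes are discarded.
#' @param seed Seed for the CV fold assignment.
#' @return An object of class `ridge_ic50_model` with the gene list,
#'   standardization parameters, coefficients, intercept, selected `lambda`,
#'   `cv_rmse` and the full CV table. Has [tidy()]/[glance()] methods.
#' @export
train_ridge_model <- function(train_expr, ic50,
                              lambda_grid = 10^seq(-3, 3, length.out = 25),
                              folds = 10, var_quantile = 0.2, seed = 1L) {
  x <- as_gene_matrix(train_expr)
  y <- resolve_ic50(ic50, colnames(x))
  n <- ncol(x)
  if (any(!is.finite(y))) abort_ip("ic50 values must be finite")
  if (folds > n) abort_ip("folds = ", folds, " exceeds the number of lines (", n, ")")
  if (any(lambda_grid <= 0)) abort_ip("lambda_grid must be positive")

  v <- apply(x, 1, var)
  keep <- v >= quantile(v, probs = var_quantile)
  if (any(v[keep] == 0)) {
    warning("dropping zero-variance gene(s) surviving the filter", call. = FALSE)
    keep <- keep & v > 0
  }
  x <- x[keep, , drop = FALSE]
  centers <- rowMeans(x)
  scales <- apply(x, 1, sd)
  z <- t((x - centers) / scales)            # lines x genes, columns mean 0 sd 1

  set.seed(as.integer(seed))
  fold_id <- sample(rep(seq_len(folds), length.out = n))
  cv <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      beta <- ridge_solve(z[tr, , drop = FALSE], y[tr], lam)
      pred <- mean(y[tr]) + z[!tr, , drop = FALSE] %*% beta
      sqrt(mean((y[!tr] - pred)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv)
  lambda <- lambda_grid[best]
  beta <- ridge_solve(z, y, lambda)

  structure(list(
    genes = rownames(x),
    center = centers, scale = scales,
    coefficients = stats::setNames(as.numeric(beta), rownames(x)),
    intercept = mean(y),
    lambda = lambda, cv_rmse = cv[best],
    cv_table = tibble::tibble(lambda = lambda_grid, rmse = cv),
    folds = folds, fold_seed = as.integer(seed)
  ), class = "ridge_ic50_model")
}

# closed-form ridge on centred response; X columns assumed centred
ridge_solve <- function(x, y, lambda) {
  yc <- y - mean(y)
  xc <- sweep(x, 2, colMeans(x))
  p <- ncol(xc)
  solve(crossprod(xc) + lambda * diag(p), crossprod(xc, yc))
}

resolve_ic50 <- function(ic50, lines) {
  if (is.data.frame(ic50)) {
    if (!all(c("line", "log_ic50") %in% names(ic50))) {
      abort_ip("ic50 tibble needs columns 'line' and 'log_ic50'")
    }
    y <- ic50$log_ic50[match(lines, ic50$line)]
    if (anyNA(y)) abort_ip("ic50 missing for some training lines")
    return(y)
  }
  if (!is.null(names(ic50))) {
    y <- ic50[match(lines, names(ic50))]
    if (anyNA(y)) abort_ip("ic50 missing for some training lines")
    return(unname(y))
  }
  if (length(ic50) != length(lines)) abort_ip("ic50 length must match training lines")
  as.numeric(ic50)
}

#' @export
print.ridge_ic50_model <- function(x, ...) {
  cat("ridge IC50 model: ", length(x$genes), " genes, lambda = ",
      format(x$lambda, digits = 4), ", CV RMSE = ",
      format(x$cv_rmse, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Predict log IC50 for tumor samples
#'
#' Applies the trained standardization (training means/sds) to the tumor
#' expression; model genes missing from the tumor matrix are imputed at the
#' training mean (standardized 0). If fewer than `min_overlap` of the model
#' genes are present, prediction refuses with an error reporting the overlap.
#'
#' @param model A `ridge_ic50_model`.
#' @param tumor_expr Gene-by-sample [expression_matrix()].
#' @param min_overlap Minimum fraction of model genes required.
#' @return A tibble with `sample`, `predicted_log_ic50`.
#' @export
predict_ic50 <- function(model, tumor_expr, min_overlap = 0.5) {
  m <- as_gene_matrix(tumor_expr)
  present <- model$genes %in% rownames(m)
  overlap <- mean(present)
  if (overlap < min_overlap) {
    abort_ip(sprintf("only %.1f%% of model genes present (threshold %.1f%%)",
                     100 * overlap, 100 * min_overlap))
  }
  z <- matrix(0, nrow = ncol(m), ncol = length(model$genes),
              dimnames = list(colnames(m), model$genes))
  idx <- which(present)
  z[, idx] <- t((m[model$genes[idx], , drop = FALSE] - model$center[idx]) /
                  model$scale[idx])
  pred <- model$intercept + as.numeric(z %*% model$coefficients)
  tibble::tibble(sample = colnames(m), predicted_log_ic50 = pred)
}

#' Compare predicted drug response between phenotypes
#'
#' One-way ANOVA or Kruskal-Wallis on predicted log IC50 by phenotype. In
#' `"auto"` mode a Shapiro-Wilk gate (alpha = 0.05 per group) selects ANOVA
#' when every group looks normal and Kruskal-Wallis otherwise.
#'
#' @param predictions Tibble with `sample` and a numeric prediction column
#'   (e.g. from [predict_ic50()]), or a vector named by sample.
#' @param labels Phenotype tibble (`sample`, `phenotype`).
#' @param test `"auto"`, `"anova"` or `"kruskal-wallis"`.
#' @return A list with `test` (method, statistic, df, p_value) and `medians`
#'   (per-group medians).
#' @export
compare_response <- function(predictions, labels,
                             test = c("auto", "anova", "kruskal-wallis")) {
  test <- match.arg(test)
  if (is.data.frame(predictions)) {
    val_col <- setdiff(names(predictions), "sample")[1]
    pv <- stats::setNames(predictions[[val_col]], predictions$sample)
  } else {
    pv <- predictions
  }
  shared <- intersect(names(pv), labels$sample)
  if (length(shared) == 0) abort_ip("no samples shared between predictions and labels")
  y <- unname(pv[shared])
  g <- droplevels(factor(labels$phenotype[match(shared, labels$sample)]))
  if (any(table(g) == 0) || nlevels(g) < 2) abort_ip("every group needs observations")
  if (test == "auto") {
    normal <- all(vapply(levels(g), function(l) {
      yy <- y[g == l]
      if (length(yy) < 3 || sd(yy) == 0) return(FALSE)
      stats::shapiro.test(yy[seq_len(min(length(yy), 5000))])$p.value > 0.05
    }, logical(1)))
    test <- if (normal) "anova" else "kruskal-wallis"
  }
  res <- if (test == "anova") {
    a <- stats::anova(stats::lm(y ~ g))
    tibble::tibble(method = "anova", statistic = a$`F value`[1],
                   df = paste(a$Df[1], a$Df[2], sep = ","),
                   p_value = a$`Pr(>F)`[1])
  } else {
    kw <- stats::kruskal.test(y, g)
    tibble::tibble(method = "kruskal-wallis", statistic = unname(kw$statistic),
                   df = as.character(unname(kw$parameter)), p_value = kw$p.value)
  }
  medians <- tibble::tibble(
    phenotype = levels(g),
    median = vapply(levels(g), function(l) median(y[g == l]), numeric(1)),
    n = as.integer(table(g))
  )
  list(test = res, medians = medians)
}
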