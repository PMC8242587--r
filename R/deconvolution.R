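#' Estimate immune cell-type fractions from bulk expression
#'
#' Plays the role a leukocyte signature matrix (LM22-style) deconvolution
#' plays in bulk immunogenomics. For each sample, the mixture and every
#' signature column are restricted to shared genes and z-scored over them; a
#' non-negative weight vector minimising the squared residual is found either
#' by non-negative least squares (`nnls`, deterministic default) or by linear
#' nu-support-vector regression over `nu in {0.25, 0.5, 0.75}`, keeping the
#' lowest-RMSE fit with negative weights truncated to zero. Solving in
#' z-space makes fractions invariant to positive rescaling of a sample;
#' weights are mapped back through each signature column's scale before
#' renormalising to the unit simplex, so noiseless mixtures are recovered
#' exactly.
#'
#' @param bulk An [expression_matrix()] of mixtures.
#' @param sig Signature matrix: genes x cell types (matrix with dimnames, or a
#'   gene-first data frame). Every column must have a positive entry.
#' @param method `"nnls"` or `"nu-svr"`.
#' @return A cell-type-by-sample tibble of class `immunophen_fractions`
#'   (columns sum to 1), with per-sample residual RMSE in the `rmse`
#'   attribute.
#' @export
deconvolve <- function(bulk, sig, method = c("nnls", "nu-svr")) {
  method <- match.arg(method)
  b <- as_gene_matrix(bulk)
  s <- if (is.matrix(sig)) sig else as_gene_matrix(sig)
  if (any(colSums(s > 0) == 0)) abort_ip("signature column(s) with no positive entry")
  shared <- intersect(rownames(b), rownames(s))
  if (length(shared) < 2) abort_ip("fewer than 2 shared genes between bulk and signature")
  b <- b[shared, , drop = FALSE]
  s <- s[shared, , drop = FALSE]
  col_sd <- apply(s, 2, sd)
  if (any(col_sd == 0)) abort_ip("constant signature column(s) over shared genes: ",
                                 paste(colnames(s)[col_sd == 0], collapse = ", "))
  sz <- scale(s)
  n_types <- ncol(s)
  fractions <- matrix(NA_real_, nrow = n_types, ncol = ncol(b),
                      dimnames = list(colnames(s), colnames(b)))
  rmse <- stats::setNames(numeric(ncol(b)), colnames(b))
  for (j in seq_len(ncol(b))) {
    y <- b[, j]
    if (sd(y) == 0) {
      warning("constant bulk sample '", colnames(b)[j],
              "'; fractions set uniform", call. = FALSE)
      fractions[, j] <- 1 / n_types
      rmse[j] <- NA_real_
      next
    }
    yz <- (y - mean(y)) / sd(y)
    w <- switch(method,
      nnls = pracma::lsqnonneg(sz, yz)$x,
      `nu-svr` = {
        best <- NULL
        for (nu in c(0.25, 0.5, 0.75)) {
          fit <- e1071::svm(x = sz, y = yz, type = "nu-regression",
                            kernel = "linear", nu = nu, scale = FALSE)
          wv <- as.numeric(crossprod(fit$coefs, fit$SV))
          wv <- pmax(wv, 0)
          r <- sqrt(mean((sz %*% wv - yz)^2))
          if (is.null(best) || r < best$r) best <- list(w = wv, r = r)
        }
        best$w
      })
    if (all(w == 0)) {
      warning("degenerate all-zero fit for sample '", colnames(b)[j],
              "'; fractions set uniform", call. = FALSE)
      fractions[, j] <- 1 / n_types
      rmse[j] <- sqrt(mean(yz^2))
      next
    }
    rmse[j] <- sqrt(mean((sz %*% w - yz)^2))
    f <- w / col_sd
    fractions[, j] <- f / sum(f)
  }
  out <- tibble::as_tibble(fractions, rownames = "cell_type")
  attr(out, "rmse") <- rmse
  attr(out, "method") <- method
  class(out) <- unique(c("immunophen_fractions", class(out)))
  out
}

#' Pairwise Pearson correlations between cell-type fractions
#'
#' @param fractions An `immunophen_fractions` tibble (cell types x samples).
#' @return A symmetric cell-type correlation matrix with unit diagonal;
#'   entries involving a constant cell type are `NA` (reported with a
#'   warning).
#' @export
cell_fraction_correlations <- function(fractions) {
  m <- as_gene_matrix(fractions)
  if (ncol(m) < 3) abort_ip("need at least 3 samples to correlate fractions")
  sds <- apply(m, 1, sd)
  cm <- suppressWarnings(stats::cor(t(m)))
  if (any(sds == 0)) {
    warning("constant cell type(s) yield undefined correlations: ",
            paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    cm[sds == 0, ] <- NA_real_
    cm[, sds == 0] <- NA_real_
  }
  diag(cm) <- 1
  cm
}
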