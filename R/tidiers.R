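#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a GET signature derivation
#' @param x A `get_derivation` object.
#' @param ... Unused.
#' @return The per-cohort candidate table (cohort, gene, pearson_r, p,
#'   adjusted_p, passed).
#' @export
tidy.get_derivation <- function(x, ...) x$by_cohort

#' One-row summary of a GET signature derivation
#' @param x A `get_derivation` object.
#' @param ... Unused.
#' @export
glance.get_derivation <- function(x, ...) {
  tibble::tibble(
    n_cohorts = length(unique(x$by_cohort$cohort)),
    n_candidates = length(unique(x$by_cohort$gene)),
    n_signature = length(x$final_signature),
    r_min = x$r_min, adj_p_max = x$adj_p_max, anchor = x$anchor
  )
}

#' Tidy a ridge IC50 model
#' @param x A `ridge_ic50_model`.
#' @param ... Unused.
#' @return One row per gene: `term`, `estimate` (standardized-scale
#'   coefficient), training `center` and `scale`.
#' @export
tidy.ridge_ic50_model <- function(x, ...) {
  tibble::tibble(term = x$genes, estimate = unname(x$coefficients),
                 center = unname(x$center), scale = unname(x$scale))
}

#' One-row summary of a ridge IC50 model
#' @param x A `ridge_ic50_model`.
#' @param ... Unused.
#' @export
glance.ridge_ic50_model <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes), lambda = x$lambda,
                 cv_rmse = x$cv_rmse, folds = x$folds,
                 fold_seed = x$fold_seed)
}

#' Tidy a Kaplan-Meier contrast
#' @param x A `km_contrast`.
#' @param ... Unused.
#' @return The per-group survival curves.
#' @export
tidy.km_contrast <- function(x, ...) x$curves

#' One-row summary of a Kaplan-Meier contrast (overall log-rank test)
#' @param x A `km_contrast`.
#' @param ... Unused.
#' @export
glance.km_contrast <- function(x, ...) x$overall
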