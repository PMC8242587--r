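#' Derive an exhausted CD8+ T-cell (GET) signature by correlation filtering
#'
#' For each cohort, every candidate gene's expression is Pearson-correlated
#' with the anchor gene's expression across samples (the anchor is `PDCD1`,
#' the PD-1 gene, by default — the reading under which distinct PD-1
#' upregulation drives the exhaustion programme). P-values are
#' Benjamini-Hochberg adjusted within each cohort; a candidate passes when
#' `adjusted_p < adj_p_max` and `|r| > r_min`. The final signature is the
#' intersection of the per-cohort passing sets, so adding cohorts or
#' tightening either threshold can only shrink it. A candidate absent from a
#' cohort fails in that cohort (with a message); the anchor itself passes
#' trivially (r = 1) when it is among the candidates.
#'
#' @param cohorts A list of [expression_matrix()] tibbles (named or not).
#' @param candidates Character vector of candidate gene identifiers.
#' @param anchor Anchor gene; must be present in every cohort.
#' @param r_min Minimum `|r|` (exclusive).
#' @param adj_p_max Maximum adjusted p (exclusive).
#' @return An object of class `get_derivation`: list with `by_cohort`
#'   (tibble: cohort, gene, pearson_r, p, adjusted_p, passed),
#'   `final_signature`, and the thresholds. Has [tidy()] and [glance()]
#'   methods.
#' @export
derive_get_signature <- function(cohorts, candidates, anchor = "PDCD1",
                                 r_min = 0.25, adj_p_max = 0.05) {
  if (!is.list(cohorts) || length(cohorts) == 0) abort_ip("'cohorts' must be a non-empty list")
  if (length(candidates) == 0) abort_ip("'candidates' must be non-empty")
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    names(cohorts) <- sprintf("cohort%d", seq_along(cohorts))
  }
  candidates <- unique(as.character(candidates))
  by_cohort <- purrr::imap_dfr(cohorts, function(expr, nm) {
    m <- as_gene_matrix(expr)
    if (!anchor %in% rownames(m)) {
      abort_ip("anchor gene '", anchor, "' absent from cohort '", nm, "'")
    }
    a <- m[anchor, ]
    if (sd(a) == 0) abort_ip("anchor gene is constant in cohort '", nm, "'")
    res <- purrr::map_dfr(candidates, function(g) {
      if (!g %in% rownames(m)) {
        return(tibble::tibble(gene = g, pearson_r = NA_real_, p = NA_real_))
      }
      x <- m[g, ]
      if (identical(g, anchor)) {
        return(tibble::tibble(gene = g, pearson_r = 1, p = 0))
      }
      if (sd(x) == 0) {
        return(tibble::tibble(gene = g, pearson_r = NA_real_, p = NA_real_))
      }
      ct <- cor.test(x, a, method = "pearson")
      tibble::tibble(gene = g, pearson_r = unname(ct$estimate), p = ct$p.value)
    })
    n_absent <- sum(is.na(res$p))
    if (n_absent > 0) {
      message(n_absent, " candidate(s) absent or constant in cohort '", nm,
              "'; treated as failed")
    }
    res$adjusted_p <- p.adjust(res$p, method = "BH")
    res$passed <- !is.na(res$adjusted_p) & res$adjusted_p < adj_p_max &
      abs(res$pearson_r) > r_min
    dplyr::bind_cols(tibble::tibble(cohort = nm), res)
  })
  passed_sets <- lapply(split(by_cohort, by_cohort$cohort),
                        function(d) d$gene[d$passed])
  final <- sort(Reduce(intersect, passed_sets))
  structure(list(by_cohort = by_cohort, final_signature = final,
                 anchor = anchor, r_min = r_min, adj_p_max = adj_p_max),
            class = "get_derivation")
}

#' @export
print.get_derivation <- function(x, ...) {
  cat("GET signature derivation: ", length(unique(x$by_cohort$gene)),
      " candidates, ", length(unique(x$by_cohort$cohort)), " cohorts\n",
      "thresholds: |r| > ", x$r_min, ", adjusted p < ", x$adj_p_max, "\n",
      "final signature (", length(x$final_signature), "): ",
      paste(x$final_signature, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Score samples on a GET signature and split at the median
#'
#' The per-sample GET score is the unnormalized ssGSEA score of the signature
#' set; samples are split into `high`/`low` groups at the cohort median, with
#' ties (including scores equal to the median) assigned to `low`.
#'
#' @param expr An [expression_matrix()] tibble.
#' @param signature Character vector of signature genes (must intersect the
#'   expression universe).
#' @param alpha Rank-weight exponent for the ssGSEA score.
#' @return A tibble with `sample`, `get_score`, `group`.
#' @export
get_score <- function(expr, signature, alpha = 0.25) {
  if (length(signature) == 0) abort_ip("empty signature")
  enr <- ssgsea_scores(expr, list(GET = signature), alpha = alpha,
                       drop_empty = FALSE)
  sc <- as_gene_matrix(enr)["GET", ]
  med <- median(sc)
  grp <- ifelse(sc > med, "high", "low")
  if (all(grp == "low")) {
    warning("degenerate median split: all samples assigned to 'low'", call. = FALSE)
  }
  tibble::tibble(sample = names(sc), get_score = unname(sc),
                 group = factor(unname(grp), levels = c("low", "high")))
}

#' Pearson correlation between two per-sample score vectors
#'
#' Two-sided p-value via the t transform with `n - 2` degrees of freedom.
#'
#' @param x,y Paired numeric vectors, length >= 3, neither constant.
#' @return A tibble with `pearson_r`, `p_value`, `n`.
#' @export
correlate_scores <- function(x, y) {
  if (length(x) != length(y)) abort_ip("x and y must be paired (equal length)")
  if (length(x) < 3) abort_ip("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort_ip("constant input has undefined correlation")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(x))
}
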