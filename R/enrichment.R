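#' Single-sample gene set enrichment (ssGSEA) scores
#'
#' For each sample, genes are ranked by expression (descending; ties broken
#' by gene identifier so results are platform-independent) and assigned rank
#' values `v = N, N-1, ..., 1` from top to bottom. Walking down the ranked
#' list, the in-set weighted empirical CDF
#' `P_in(i) = sum(v_k^alpha, k <= i, k in G) / sum(v_g^alpha, g in G)`
#' and the out-of-set unweighted CDF
#' `P_out(i) = #(k <= i, k not in G) / (N - |G|)`
#' are accumulated; the score is the sum over all positions of
#' `P_in(i) - P_out(i)`. Because only ranks enter, scores are invariant under
#' any strictly increasing transform of a sample's expression values.
#'
#' @param expr An [expression_matrix()] tibble.
#' @param sets Named list of gene identifier vectors (e.g. from [read_gmt()]).
#' @param alpha Rank-weight exponent, `>= 0`; 0.25 is the conventional
#'   default.
#' @param normalize If `TRUE`, rescale via [normalize_enrichment()].
#' @param drop_empty If `TRUE` (default), sets with no genes in the
#'   expression universe are dropped with a warning; otherwise they are an
#'   error. A set covering the whole universe is always an error (the
#'   out-of-set CDF is undefined).
#' @return A set-by-sample tibble of class `immunophen_enrich` with `alpha`
#'   and `normalized` attributes.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = FALSE,
                          drop_empty = TRUE) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort_ip("'sets' must be a named list of gene vectors")
  }
  if (!is_scalar_number(alpha) || alpha < 0) abort_ip("alpha must be >= 0")
  m <- as_gene_matrix(expr)
  genes <- rownames(m)
  n <- nrow(m)
  kept <- lapply(sets, function(g) intersect(unique(g), genes))
  sizes <- lengths(kept)
  if (any(sizes == 0)) {
    if (drop_empty && any(sizes > 0)) {
      warning("dropping gene set(s) with empty intersection: ",
              paste(names(sets)[sizes == 0], collapse = ", "), call. = FALSE)
      kept <- kept[sizes > 0]
    } else {
      abort_ip("gene set(s) with empty expression-universe intersection: ",
               paste(names(sets)[sizes == 0], collapse = ", "))
    }
  }
  if (any(lengths(kept) == n)) {
    abort_ip("gene set covers the entire gene universe; out-of-set CDF undefined")
  }
  member <- vapply(kept, function(g) genes %in% g, logical(n))
  member <- matrix(member, nrow = n,
                   dimnames = list(genes, names(kept)))
  v_alpha <- (n:1)^alpha
  scores <- matrix(NA_real_, nrow = ncol(member), ncol = ncol(m),
                   dimnames = list(colnames(member), colnames(m)))
  for (j in seq_len(ncol(m))) {
    ord <- order(-m[, j], genes)
    mem_j <- member[ord, , drop = FALSE]
    for (s in seq_len(ncol(mem_j))) {
      ins <- mem_j[, s]
      w <- ifelse(ins, v_alpha, 0)
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ins) / (n - sum(ins))
      scores[s, j] <- sum(p_in - p_out)
    }
  }
  out <- enrichment_tbl(scores, alpha = alpha, normalized = FALSE)
  if (normalize) normalize_enrichment(out) else out
}

#' Rescale an enrichment matrix by its global range
#'
#' Every score is divided by `max - min` taken over all entries. The
#' transform is monotone per sample, so within-set sample orderings are
#' preserved. It is deliberately not idempotent (a second application rescales
#' again); the `normalized` attribute guards against accidental reapplication
#' with a warning.
#'
#' @param x An `immunophen_enrich` tibble.
#' @return The rescaled tibble with `normalized = TRUE`.
#' @export
normalize_enrichment <- function(x) {
  if (isTRUE(attr(x, "normalized"))) {
    warning("enrichment matrix already normalized; rescaling again", call. = FALSE)
  }
  m <- as_gene_matrix(x)
  rng <- max(m) - min(m)
  if (rng == 0) abort_ip("constant enrichment matrix cannot be normalized")
  out <- enrichment_tbl(m / rng, alpha = attr(x, "alpha"), normalized = TRUE)
  out
}

#' ESTIMATE-style microenvironment scores and tumor purity
#'
#' Stromal and immune scores are the unnormalized ssGSEA scores of the two
#' supplied gene lists; their sum is the ESTIMATE score, a proxy for total
#' non-tumor content, which is mapped to tumor purity by [tumor_purity()].
#' The real 141-gene stromal/immune signatures are inputs, not shipped.
#'
#' @param expr An [expression_matrix()] tibble.
#' @param stromal_genes,immune_genes Character vectors of signature genes.
#' @param alpha Rank-weight exponent passed to [ssgsea_scores()].
#' @return A tibble with columns `sample`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `purity`.
#' @export
estimate_scores <- function(expr, stromal_genes, immune_genes, alpha = 0.25) {
  enr <- ssgsea_scores(expr, list(stromal = stromal_genes, immune = immune_genes),
                       alpha = alpha, drop_empty = FALSE)
  m <- as_gene_matrix(enr)
  est <- m["stromal", ] + m["immune", ]
  tibble::tibble(
    sample = colnames(m),
    stromal_score = unname(m["stromal", ]),
    immune_score = unname(m["immune", ]),
    estimate_score = unname(est),
    purity = tumor_purity(unname(est))
  )
}

#' Cosine transform from ESTIMATE score to tumor purity
#'
#' `purity = cos(c0 + c1 * estimate_score)`, clamped to `[0, 1]` with a
#' warning when clamping occurs. The default constants are the published
#' calibration of the cosine purity formula; purity is strictly decreasing in
#' the score over the pre-clamp domain.
#'
#' @param estimate_score Numeric vector of ESTIMATE scores.
#' @param c0,c1 Calibration constants.
#' @return Purity values in `[0, 1]`.
#' @examples
#' tumor_purity(0)     # cos(0.6049872018) = 0.8225094
#' @export
tumor_purity <- function(estimate_score, c0 = 0.6049872018, c1 = 0.0001467884) {
  raw <- cos(c0 + c1 * estimate_score)
  if (any(raw < 0 | raw > 1)) {
    warning(sum(raw < 0 | raw > 1),
            " purity value(s) outside [0, 1] clamped", call. = FALSE)
  }
  pmin(pmax(raw, 0), 1)
}
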