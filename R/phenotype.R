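#' Classify samples into immune-H/M/L phenotypes
#'
#' Each gene-set row of the enrichment matrix is z-scored across samples
#' (constant rows are dropped with a warning), samples are agglomeratively
#' clustered (Euclidean distance, Ward linkage) and the tree is cut at `k`
#' clusters. Clusters are ranked by their mean z-scored enrichment over all
#' sets, descending; for `k = 3` the ranks map to `immune-H`, `immune-M`,
#' `immune-L`. Ties between cluster means are broken by cluster size
#' (descending) then cluster id, with a message. The procedure has no random
#' initialisation, so repeated runs on identical input agree exactly.
#'
#' @param enrich A set-by-sample `immunophen_enrich` tibble (or any
#'   set-first numeric table).
#' @param k Number of clusters, `>= 2`; the pipeline uses 3.
#' @param linkage Agglomeration method passed to [stats::hclust()];
#'   `"ward.D2"` is Ward's criterion on Euclidean distances.
#' @return A tibble with columns `sample`, `cluster_id`, `phenotype`
#'   (factor, levels immune-L < immune-M < immune-H), carrying the per-cluster
#'   mean enrichment and linkage as attributes.
#' @export
classify_phenotypes <- function(enrich, k = 3, linkage = "ward.D2") {
  m <- as_gene_matrix(enrich)
  if (!is_scalar_number(k) || k < 2) abort_ip("k must be an integer >= 2")
  k <- as.integer(k)
  if (k > ncol(m)) abort_ip("k = ", k, " exceeds the number of samples (", ncol(m), ")")
  sds <- apply(m, 1, sd)
  if (any(sds == 0)) {
    warning("dropping constant enrichment row(s): ",
            paste(rownames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) == 0) abort_ip("no non-constant enrichment rows left to cluster on")
  z <- t(scale(t(m)))
  hc <- stats::hclust(stats::dist(t(z)), method = linkage)
  cl <- stats::cutree(hc, k = k)
  overall <- colMeans(z)
  cl_mean <- tapply(overall, cl, mean)
  cl_size <- tabulate(cl, nbins = k)
  ord <- order(-cl_mean, -cl_size[as.integer(names(cl_mean))],
               as.integer(names(cl_mean)))
  if (anyDuplicated(round(cl_mean, 12))) {
    message("tied cluster means broken by size then cluster id")
  }
  labels <- if (k == 3) c("immune-H", "immune-M", "immune-L") else
    sprintf("immune-R%d", seq_len(k))
  lab_by_cluster <- stats::setNames(labels, names(cl_mean)[ord])
  pheno <- lab_by_cluster[as.character(cl)]
  lev <- if (k == 3) phenotype_levels else rev(labels)
  out <- tibble::tibble(
    sample = colnames(m),
    cluster_id = as.integer(cl),
    phenotype = factor(unname(pheno), levels = lev)
  )
  attr(out, "cluster_means") <- cl_mean
  attr(out, "linkage") <- linkage
  class(out) <- unique(c("immunophen_phenotypes", class(out)))
  out
}

#' Project samples onto principal components
#'
#' Rows (features) are centered; sample coordinates are the projections onto
#' the top singular directions of the centered matrix. Each component's sign
#' is fixed so that its largest-magnitude feature loading is positive, making
#' the output deterministic across platforms.
#'
#' @param x A feature-by-sample numeric table (expression or enrichment
#'   tibble, or a matrix with rownames/colnames).
#' @param n_components Number of components, at most `min(features, samples)`.
#' @return A tibble with columns `sample`, `PC1`, ..., plus a
#'   `variance_explained` attribute.
#' @export
pca_projection <- function(x, n_components = 3) {
  m <- if (is.matrix(x)) x else as_gene_matrix(x)
  if (n_components > min(dim(m))) {
    abort_ip("n_components = ", n_components, " exceeds min(features, samples) = ",
             min(dim(m)))
  }
  centered <- m - rowMeans(m)
  sv <- svd(centered, nu = n_components, nv = n_components)
  for (i in seq_len(n_components)) {
    top <- which.max(abs(sv$u[, i]))
    if (sv$u[top, i] < 0) {
      sv$u[, i] <- -sv$u[, i]
      sv$v[, i] <- -sv$v[, i]
    }
  }
  coords <- sweep(sv$v, 2, sv$d[seq_len(n_components)], "*")
  colnames(coords) <- paste0("PC", seq_len(n_components))
  out <- tibble::as_tibble(coords)
  out <- dplyr::bind_cols(tibble::tibble(sample = colnames(m)), out)
  attr(out, "variance_explained") <- sv$d^2 / sum(sv$d^2)
  attr(out, "loadings") <- sv$u
  out
}

#' Compare a per-sample score between phenotype groups
#'
#' Kruskal-Wallis across all groups, or all pairwise two-sided Wilcoxon
#' rank-sum tests, on a tidy table of scores and group labels.
#'
#' @param data A data frame holding the score and group columns.
#' @param score,group Column names (tidy-eval) of the numeric score and the
#'   group label.
#' @param test `"kruskal-wallis"` (one row) or `"wilcoxon-pairwise"` (one row
#'   per group pair).
#' @return A tibble of test results.
#' @export
compare_scores_by_phenotype <- function(data, score, group,
                                        test = c("kruskal-wallis", "wilcoxon-pairwise")) {
  test <- match.arg(test)
  sc <- dplyr::pull(data, {{ score }})
  gr <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (nlevels(gr) < 2) abort_ip("need at least 2 non-empty groups")
  if (any(tabulate(gr) == 0)) abort_ip("every group needs at least one observation")
  if (test == "kruskal-wallis") {
    kw <- stats::kruskal.test(sc, gr)
    return(tibble::tibble(method = "kruskal-wallis",
                          statistic = unname(kw$statistic),
                          df = unname(kw$parameter),
                          p_value = kw$p.value))
  }
  pairs <- utils::combn(levels(gr), 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    w <- suppressWarnings(stats::wilcox.test(sc[gr == p[1]], sc[gr == p[2]]))
    tibble::tibble(method = "wilcoxon", group1 = p[1], group2 = p[2],
                   statistic = unname(w$statistic), p_value = w$p.value)
  })
}
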