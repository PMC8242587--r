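#' Tumor mutation burden per sample
#'
#' TMB is the number of somatic records per megabase of surveyed genome.
#' The denominator is configurable (the 38 Mb default is the usual exome
#' capture size); `log2_tmb = log2(tmb + pseudocount)`, reported as `NA` for
#' zero-burden samples when the pseudocount is 0.
#'
#' @param maf Mutation tibble (see [read_maf()]).
#' @param samples Optional sample universe; samples absent from `maf` get
#'   count 0.
#' @param capture_size_mb Surveyed megabases, `> 0`.
#' @param pseudocount Added inside the log2.
#' @param classifications Optional include-list of variant classifications;
#'   default counts every record.
#' @return A tibble with `sample`, `mutation_count`, `tmb`, `log2_tmb`.
#' @export
compute_tmb <- function(maf, samples = NULL, capture_size_mb = 38,
                        pseudocount = 0, classifications = NULL) {
  if (!is_scalar_number(capture_size_mb) || capture_size_mb <= 0) {
    abort_ip("capture_size_mb must be > 0")
  }
  universe <- unique(c(samples, maf$sample))
  if (!is.null(classifications)) {
    maf <- maf[maf$variant_classification %in% classifications, , drop = FALSE]
  }
  counts <- table(factor(maf$sample, levels = universe))
  tmb <- as.numeric(counts) / capture_size_mb
  shifted <- tmb + pseudocount
  tibble::tibble(
    sample = universe,
    mutation_count = as.integer(counts),
    tmb = tmb,
    log2_tmb = ifelse(shifted > 0, log2(shifted), NA_real_)
  )
}

#' MATH intratumor-heterogeneity score
#'
#' Mutant-allele tumor heterogeneity: `100 * MAD / median` of a sample's
#' variant allele fractions, where MAD is the median absolute deviation
#' scaled by the 1.4826 normal-consistency factor. Wider VAF spread means
#' higher heterogeneity; the ratio is invariant under positive scaling of
#' the VAFs.
#'
#' @param vafs Numeric vector of variant allele fractions in `(0, 1]`, at
#'   least two.
#' @return The MATH score (single number).
#' @examples
#' math_score(c(0.2, 0.25, 0.3))  # 29.652
#' @export
math_score <- function(vafs) {
  if (length(vafs) < 2) abort_ip("MATH needs at least 2 VAFs")
  if (any(!is.finite(vafs)) || any(vafs <= 0) || any(vafs > 1)) {
    abort_ip("VAFs must lie in (0, 1]")
  }
  med <- median(vafs)
  100 * 1.4826 * median(abs(vafs - med)) / med
}

#' Per-sample MATH scores from a mutation table
#'
#' @param maf Mutation tibble; zero-depth and zero-alt records are excluded.
#' @param min_vafs Minimum VAF count per sample (default 2); samples below it
#'   get `NA`.
#' @return A tibble with `sample`, `n_vaf`, `math`.
#' @export
math_by_sample <- function(maf, min_vafs = 2) {
  v <- maf_vaf(maf)
  v <- v[v$vaf > 0, , drop = FALSE]
  v |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(
      n_vaf = dplyr::n(),
      math = if (dplyr::n() >= min_vafs) math_score(.data$vaf) else NA_real_,
      .groups = "drop"
    )
}

#' Recurrently mutated sites
#'
#' Sites are keyed by `(chromosome, position)` (1-based) and reported when
#' their record count strictly exceeds `min_n`, matching the `N > 5`
#' convention for recurrent SNP sites.
#'
#' @param maf Mutation tibble.
#' @param min_n Strict lower bound on the count.
#' @return A tibble `chromosome`, `position`, `count`, most recurrent first.
#' @export
recurrent_site_counts <- function(maf, min_n = 5) {
  if (min_n < 0) abort_ip("min_n must be >= 0")
  maf |>
    dplyr::count(.data$chromosome, .data$position, name = "count") |>
    dplyr::filter(.data$count > min_n) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$chromosome, .data$position)
}

#' Pearson chi-square test on a contingency table
#'
#' `sum((O - E)^2 / E)` with expected counts from the product of margins,
#' no continuity correction, `df = (r - 1)(c - 1)` and an upper-tail
#' chi-square p-value.
#'
#' @param table An r x c matrix/table of non-negative integer counts with all
#'   row and column sums positive.
#' @return A tibble with `statistic`, `df`, `p_value`.
#' @export
chi_square_test <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(abs(m - round(m)) > 1e-8)) {
    abort_ip("contingency table must hold non-negative integer counts")
  }
  if (sum(m) <= 0) abort_ip("contingency table total must be positive")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort_ip("contingency table has a zero row or column margin")
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(res$statistic),
                 df = as.integer(res$parameter),
                 p_value = res$p.value)
}

#' Cross-tabulate a categorical feature by phenotype
#'
#' Joins per-sample phenotype labels with a per-sample categorical feature and
#' counts. Row order is immune-L, immune-M, immune-H; feature levels keep
#' first-seen order. Samples with a missing feature value are dropped with a
#' message stating how many.
#'
#' @param labels Phenotype tibble from [classify_phenotypes()] (columns
#'   `sample`, `phenotype`).
#' @param feature A data frame with columns `sample` and one feature column,
#'   or a vector named by sample.
#' @return A phenotype x level contingency matrix suitable for
#'   [chi_square_test()].
#' @export
phenotype_feature_table <- function(labels, feature) {
  if (is.data.frame(feature)) {
    if (!"sample" %in% names(feature) || ncol(feature) != 2) {
      abort_ip("'feature' data frame must have columns: sample, <feature>")
    }
    feat_col <- setdiff(names(feature), "sample")
    fv <- stats::setNames(feature[[feat_col]], feature$sample)
  } else {
    if (is.null(names(feature))) abort_ip("'feature' vector must be named by sample")
    fv <- feature
  }
  shared <- intersect(labels$sample, names(fv))
  if (length(shared) == 0) abort_ip("no samples shared between labels and feature")
  f <- fv[shared]
  ph <- labels$phenotype[match(shared, labels$sample)]
  miss <- is.na(f)
  if (any(miss)) {
    message(sum(miss), " sample(s) with missing feature value dropped")
    f <- f[!miss]; ph <- ph[!miss]
  }
  lev <- if (is.factor(f)) levels(droplevels(f)) else unique(as.character(f))
  tab <- table(phenotype = factor(ph, levels = levels(ph)),
               level = factor(as.character(f), levels = lev))
  unclass(tab)
}
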