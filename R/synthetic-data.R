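#' Configure a synthetic bulk-tumor cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: each bulk sample is a purity-weighted mixture of one shared tumor
#' profile and a set of cell-type profiles, with a three-level planted
#' infiltration gradient (immune-L < immune-M < immune-H), multiplicative
#' log-normal noise, Beta-distributed variant allele fractions for the
#' mutation table and phenotype-dependent exponential survival hazards.
#'
#' @param n_genes,n_samples,n_cell_types,markers_per_type Cohort dimensions.
#'   Marker genes are disjoint blocks, so `markers_per_type * n_cell_types`
#'   must not exceed `n_genes`.
#' @param phenotype_proportions Length-3 simplex vector: planted fractions of
#'   immune-L, immune-M, immune-H samples. Default mirrors the roughly
#'   40/40/20 split seen in large glioma cohorts.
#' @param infiltration_levels Mean non-tumor (immune + stromal) fraction for
#'   the L, M and H groups; must be strictly increasing.
#' @param noise_sd Log-scale Gaussian noise sd applied multiplicatively.
#' @param marker_fold Fold-elevation of each cell type's markers in its own
#'   profile relative to baseline.
#' @param vaf_beta_params Two positive Beta shape parameters for variant
#'   allele fractions.
#' @param hazard_multipliers Per-phenotype (L, M, H) multipliers on the
#'   baseline exponential hazard; the default reproduces the roughly 1 / 1.4 /
#'   2 hazard ordering reported for immune-L/M/H glioma phenotypes.
#' @param base_median_survival Baseline (immune-L) median survival time, in
#'   months.
#' @param concentration Beta concentration of the per-sample non-tumor
#'   fraction around its phenotype mean (higher = tighter).
#' @param seed Integer seed; every draw is reproducible given it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1000, n_samples = 300, n_cell_types = 5,
                          markers_per_type = 20,
                          phenotype_proportions = c(0.4, 0.4, 0.2),
                          infiltration_levels = c(0.10, 0.30, 0.60),
                          noise_sd = 0.2, marker_fold = 8,
                          vaf_beta_params = c(2, 5),
                          hazard_multipliers = c(1, 1.4, 2),
                          base_median_survival = 24,
                          concentration = 250, seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_cell_types = as.integer(n_cell_types),
    markers_per_type = as.integer(markers_per_type),
    phenotype_proportions = phenotype_proportions,
    infiltration_levels = infiltration_levels,
    noise_sd = noise_sd, marker_fold = marker_fold,
    vaf_beta_params = vaf_beta_params,
    hazard_multipliers = hazard_multipliers,
    base_median_survival = base_median_survival,
    concentration = concentration, seed = as.integer(seed)
  )
  stopifnot(cfg$n_genes > 0, cfg$n_samples > 0, cfg$n_cell_types > 0,
            cfg$markers_per_type > 0)
  if (abs(sum(phenotype_proportions) - 1) > 1e-9 || length(phenotype_proportions) != 3 ||
      any(phenotype_proportions < 0)) {
    abort_ip("phenotype_proportions must be a length-3 vector on the simplex")
  }
  if (length(infiltration_levels) != 3 || any(diff(infiltration_levels) <= 0) ||
      any(infiltration_levels <= 0) || any(infiltration_levels >= 1)) {
    abort_ip("infiltration_levels must be 3 strictly increasing values in (0, 1)")
  }
  if (cfg$markers_per_type * cfg$n_cell_types > cfg$n_genes) {
    abort_ip("markers_per_type * n_cell_types must not exceed n_genes")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) abort_ip("noise_sd must be >= 0")
  if (length(vaf_beta_params) != 2 || any(vaf_beta_params <= 0)) {
    abort_ip("vaf_beta_params must be two positive shape parameters")
  }
  if (length(hazard_multipliers) != 3 || any(hazard_multipliers <= 0)) {
    abort_ip("hazard_multipliers must be 3 positive scalars")
  }
  structure(cfg, class = "cohort_config")
}

phenotype_levels <- c("immune-L", "immune-M", "immune-H")

# immune-flavoured cell type names; the last planted type is always stromal
cell_type_names <- function(n) {
  immune <- c("T.cells.CD8", "NK.cells", "B.cells", "Macrophages",
              "Dendritic.cells", "Monocytes", "Mast.cells", "Neutrophils",
              "T.cells.CD4", "Plasma.cells", "Tregs", "T.cells.gamma.delta",
              "Eosinophils", "T.cells.follicular.helper", "NK.cells.resting",
              "Macrophages.M1", "Macrophages.M2", "B.cells.memory",
              "Dendritic.cells.resting", "Mast.cells.resting", "Monocytes.classical")
  if (n == 1L) return("Fibroblasts")
  k <- n - 1L
  imm <- if (k <= length(immune)) immune[seq_len(k)] else
    c(immune, sprintf("Immune.type.%02d", seq_len(k - length(immune))))[seq_len(k)]
  c(imm, "Fibroblasts")
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Expression for gene g in sample j is
#' `purity_j * T_g + (1 - purity_j) * sum_c f_cj * C_gc`, multiplied by
#' `exp(N(0, noise_sd))`. `T` is a shared tumor profile, `C` holds one profile
#' per cell type with that type's markers elevated `marker_fold`-fold, `f` are
#' Dirichlet cell-type fractions within the non-tumor compartment, and purity
#' is one minus a Beta draw centred on the planted phenotype's infiltration
#' level. Survival times are exponential with a per-phenotype hazard
#' multiplier, administratively censored at the 75th percentile of drawn times.
#'
#' @param config A [cohort_config()].
#' @return A list with `expression` (an [expression_matrix()]), `clinical`
#'   (sample, time, event, phenotype) and `truth` (purity, cell fractions,
#'   planted labels, hazard multipliers, marker gene blocks, profiles).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ng <- config$n_genes; ns <- config$n_samples; nc <- config$n_cell_types
  genes <- sprintf("G%06d", seq_len(ng))
  samples <- sprintf("S%04d", seq_len(ns))
  types <- cell_type_names(nc)

  markers <- split(genes[seq_len(nc * config$markers_per_type)],
                   rep(seq_len(nc), each = config$markers_per_type))
  names(markers) <- types

  tumor_profile <- rlnorm(ng, meanlog = 2, sdlog = 1)
  cell_profiles <- matrix(rlnorm(ng * nc, meanlog = 2, sdlog = 1), nrow = ng,
                          dimnames = list(genes, types))
  for (c in seq_len(nc)) {
    idx <- match(markers[[c]], genes)
    cell_profiles[idx, c] <- cell_profiles[idx, c] * config$marker_fold
  }

  # planted labels: deterministic counts, shuffled order
  counts <- diff(c(0, round(cumsum(config$phenotype_proportions) * ns)))
  label <- sample(rep(phenotype_levels, times = counts))
  lvl_idx <- match(label, phenotype_levels)

  nontumor <- rbeta(ns, config$infiltration_levels[lvl_idx] * config$concentration,
                    (1 - config$infiltration_levels[lvl_idx]) * config$concentration)
  purity <- 1 - nontumor
  fractions <- rdirichlet_cols(ns, rep(25, nc))
  dimnames(fractions) <- list(types, samples)

  clean <- outer(tumor_profile, purity) +
    cell_profiles %*% sweep(fractions, 2, nontumor, "*")
  noise <- if (config$noise_sd > 0) {
    matrix(exp(rnorm(ng * ns, 0, config$noise_sd)), nrow = ng)
  } else 1
  values <- clean * noise
  dimnames(values) <- list(genes, samples)

  mult <- config$hazard_multipliers[lvl_idx]
  rate0 <- log(2) / config$base_median_survival
  t_raw <- rexp(ns, rate = rate0 * mult)
  horizon <- unname(quantile(t_raw, 0.75))
  clinical <- tibble::tibble(
    sample = samples,
    time = pmin(t_raw, horizon),
    event = as.integer(t_raw <= horizon),
    phenotype = factor(label, levels = phenotype_levels)
  )

  truth <- structure(list(
    purity = stats::setNames(purity, samples),
    fractions = fractions,
    phenotype = stats::setNames(label, samples),
    hazard_multiplier = stats::setNames(mult, samples),
    markers = markers,
    tumor_profile = stats::setNames(tumor_profile, genes),
    cell_profiles = cell_profiles,
    config = config
  ), class = "cohort_truth")

  list(expression = expression_matrix(values, unit = "COUNTS"),
       clinical = clinical, truth = truth)
}

#' Marker gene sets matching a simulated cohort
#'
#' One marker set per planted cell type plus two meta-sets: `immune` (union of
#' the immune cell types' markers) and `stromal` (markers of the stromal
#' type). Every member is in the cohort's gene universe and the per-type sets
#' are disjoint by construction.
#'
#' @param truth The `truth` component of [simulate_cohort()].
#' @return A named list of gene identifier vectors
#'   (`n_cell_types + 2` sets).
#' @export
simulate_gene_sets <- function(truth) {
  stopifnot(inherits(truth, "cohort_truth"))
  markers <- truth$markers
  stromal_types <- grepl("Fibroblast", names(markers))
  if (!any(stromal_types)) stromal_types <- seq_along(markers) == length(markers)
  sets <- c(markers,
            list(stromal = unname(unlist(markers[stromal_types])),
                 immune = unname(unlist(markers[!stromal_types]))))
  sets
}

#' Generate a MAF-like mutation table with Beta-distributed VAFs
#'
#' Per-sample mutation counts are Poisson (or supplied via a generating
#' function); each variant's allele fraction is drawn from
#' `Beta(vaf_beta_params)` and converted to read counts at the given depth by
#' rounding, so the realised VAF matches the draw to within half a read.
#'
#' @param sample_ids Character vector of sample identifiers.
#' @param mutations_per_sample Either a single Poisson mean or a
#'   `function(n)` returning `n` non-negative integer counts.
#' @param depth Sequencing depth per variant.
#' @param vaf_beta_params Two positive Beta shape parameters.
#' @param genes Gene universe to sample mutated genes from.
#' @param hotspot Optional `list(chromosome=, position=, n=)` planting `n`
#'   extra records at a fixed recurrent site.
#' @param seed Integer seed.
#' @return A mutation tibble in the layout of [read_maf()].
#' @export
simulate_maf <- function(sample_ids, mutations_per_sample = 40, depth = 100L,
                         vaf_beta_params = c(2, 5),
                         genes = sprintf("G%06d", 1:1000),
                         hotspot = NULL, seed = 1L) {
  if (any(vaf_beta_params <= 0)) abort_ip("Beta shape parameters must be positive")
  set.seed(as.integer(seed))
  n_mut <- if (is.function(mutations_per_sample)) {
    mutations_per_sample(length(sample_ids))
  } else {
    rpois(length(sample_ids), mutations_per_sample)
  }
  total <- sum(n_mut)
  vaf <- rbeta(total, vaf_beta_params[1], vaf_beta_params[2])
  alt <- pmin(pmax(as.integer(round(depth * vaf)), 1L), depth - 1L)
  out <- tibble::tibble(
    sample = rep(sample_ids, times = n_mut),
    gene = sample(genes, total, replace = TRUE),
    chromosome = as.character(sample(1:22, total, replace = TRUE)),
    position = sample.int(1e8, total, replace = TRUE),
    variant_classification = sample(
      c("Missense_Mutation", "Nonsense_Mutation", "Silent", "Splice_Site"),
      total, replace = TRUE, prob = c(0.6, 0.1, 0.2, 0.1)),
    ref_count = depth - alt,
    alt_count = alt
  )
  if (!is.null(hotspot)) {
    hs_vaf <- rbeta(hotspot$n, vaf_beta_params[1], vaf_beta_params[2])
    hs_alt <- pmin(pmax(as.integer(round(depth * hs_vaf)), 1L), depth - 1L)
    out <- dplyr::bind_rows(out, tibble::tibble(
      sample = sample(sample_ids, hotspot$n, replace = TRUE),
      gene = hotspot$gene %||% "HOTSPOT1",
      chromosome = as.character(hotspot$chromosome),
      position = as.integer(hotspot$position),
      variant_classification = "Missense_Mutation",
      ref_count = depth - hs_alt,
      alt_count = hs_alt
    ))
  }
  out
}

#' Generate cell-line training data with a linear log-IC50 model
#'
#' Expression is log-normal; log IC50 is an intercept plus a linear
#' combination of the first `n_effect_genes` genes' raw expression plus
#' Gaussian noise. The true coefficients are returned so regression stages can
#' be checked for parameter recovery.
#'
#' @param n_lines Number of cell lines.
#' @param n_genes Number of genes.
#' @param n_effect_genes Number of genes with non-zero effect on IC50.
#' @param effect_sd Coefficient scale (raw-expression units).
#' @param noise_sd Gaussian noise sd on log IC50.
#' @param intercept Model intercept.
#' @param seed Integer seed.
#' @return A list with `expression` (genes x lines), `ic50`
#'   (tibble of line, log_ic50) and `truth` (named coefficients, intercept,
#'   noise_sd).
#' @export
simulate_cellline_training <- function(n_lines = 200, n_genes = 500,
                                       n_effect_genes = 20, effect_sd = 0.2,
                                       noise_sd = 0.5, intercept = 2,
                                       seed = 1L) {
  if (n_effect_genes > n_genes) abort_ip("n_effect_genes must be <= n_genes")
  set.seed(as.integer(seed))
  genes <- sprintf("G%06d", seq_len(n_genes))
  lines <- sprintf("CL%04d", seq_len(n_lines))
  x <- matrix(rlnorm(n_genes * n_lines, meanlog = 2, sdlog = 0.5),
              nrow = n_genes, dimnames = list(genes, lines))
  beta <- stats::setNames(rnorm(n_effect_genes, 0, effect_sd),
                          genes[seq_len(n_effect_genes)])
  y <- intercept + as.numeric(crossprod(x[names(beta), , drop = FALSE], beta)) +
    rnorm(n_lines, 0, noise_sd)
  list(expression = expression_matrix(x, unit = "COUNTS"),
       ic50 = tibble::tibble(line = lines, log_ic50 = y),
       truth = list(coefficients = beta, intercept = intercept,
                    noise_sd = noise_sd))
}

#' Generate cohorts for exhaustion-signature derivation tests
#'
#' Builds `n_cohorts` expression matrices containing an anchor gene (`PDCD1`),
#' planted candidates correlated with the anchor at Pearson `r` (named after
#' the canonical exhaustion partners CD27, ICOS, RUNX2, CXCR6), independent
#' null candidates and background genes. Values are shifted Gaussians (mean
#' 100, sd 10), so the planted correlation is exact in distribution.
#'
#' @param n_samples Samples per cohort.
#' @param r Planted Pearson correlation of the correlated candidates.
#' @param n_correlated Number of correlated candidates (up to 4 canonical
#'   names; extras are `GETX##`).
#' @param n_null Number of independent null candidates.
#' @param n_background Additional unrelated genes.
#' @param n_cohorts Number of cohorts.
#' @param seed Integer seed.
#' @return A list with `cohorts` (list of expression matrices), `candidates`,
#'   `correlated`, `null_genes` and `anchor`.
#' @export
simulate_get_cohorts <- function(n_samples = 200, r = 0.6, n_correlated = 4,
                                 n_null = 10, n_background = 50,
                                 n_cohorts = 2, seed = 1L) {
  stopifnot(abs(r) < 1, n_correlated >= 1)
  set.seed(as.integer(seed))
  canonical <- c("CD27", "ICOS", "RUNX2", "CXCR6")
  corr_names <- if (n_correlated <= 4) canonical[seq_len(n_correlated)] else
    c(canonical, sprintf("GETX%02d", seq_len(n_correlated - 4)))
  null_names <- sprintf("NULLG%02d", seq_len(n_null))
  bg_names <- sprintf("BG%04d", seq_len(n_background))
  cohorts <- lapply(seq_len(n_cohorts), function(k) {
    anchor_z <- rnorm(n_samples)
    corr <- vapply(seq_len(n_correlated), function(i) {
      r * anchor_z + sqrt(1 - r^2) * rnorm(n_samples)
    }, numeric(n_samples))
    nulls <- matrix(rnorm(n_samples * n_null), ncol = n_null)
    bg <- matrix(rnorm(n_samples * n_background), ncol = n_background)
    m <- t(cbind(anchor_z, corr, nulls, bg)) * 10 + 100
    dimnames(m) <- list(c("PDCD1", corr_names, null_names, bg_names),
                        sprintf("S%04d", seq_len(n_samples)))
    expression_matrix(m, unit = "COUNTS")
  })
  names(cohorts) <- sprintf("cohort%d", seq_len(n_cohorts))
  list(cohorts = cohorts,
       candidates = c("PDCD1", corr_names, null_names),
       correlated = corr_names, null_genes = null_names, anchor = "PDCD1")
}
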