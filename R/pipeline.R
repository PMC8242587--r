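#' Run the full immunogenomic pipeline from one configuration
#'
#' Orchestrates the stages in dependency order — enrichment scoring,
#' phenotype classification, ESTIMATE-style scores, deconvolution, mutation
#' statistics, GET signature scoring, survival contrasts and drug-response
#' prediction — writing one table per stage plus a JSON manifest recording
#' inputs (with MD5 hashes for file inputs), parameters and seeds, so a
#' results bundle is self-describing and reproducible. Enrichment and
#' classification are mandatory; any other enabled stage that fails is
#' recorded in the manifest without aborting the rest.
#'
#' @param config A named list, or the path to a YAML file holding one.
#'   Recognised entries:
#' \describe{
#'   \item{expression}{Path to a TSV/CSV or an [expression_matrix()] (required).}
#'   \item{unit}{Expression unit tag (default `"TPM"`); FPKM input is
#'     converted to TPM before scoring.}
#'   \item{gene_sets}{GMT path or named list of gene vectors (required).}
#'   \item{stromal_set,immune_set}{Names of the two meta-sets used for
#'     ESTIMATE scoring (defaults `"stromal"`, `"immune"`).}
#'   \item{maf}{MAF path or mutation tibble (optional).}
#'   \item{clinical}{Clinical CSV path or tibble (optional).}
#'   \item{signature_matrix}{Deconvolution signature path/matrix (optional).}
#'   \item{train_expression,train_ic50}{Cell-line training data (optional).}
#'   \item{get_candidates,get_anchor}{Candidate genes and anchor for GET
#'     scoring (optional; the derived or supplied signature is scored).}
#'   \item{params}{List: `alpha`, `k`, `capture_size_mb`, `r_min`,
#'     `adj_p_max`, `lambda_grid`, `folds`, `var_quantile`, `seed`.}
#'   \item{output_dir}{Directory for the results bundle (required).}
#' }
#' @return Invisibly, a list of per-stage results plus the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$expression)) abort_ip("config must name an expression input")
  if (is.null(config$gene_sets)) abort_ip("config must name a gene_sets input")
  if (is.null(config$output_dir)) abort_ip("config must name an output_dir")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  p <- utils::modifyList(list(
    alpha = 0.25, k = 3, capture_size_mb = 38, r_min = 0.25, adj_p_max = 0.05,
    lambda_grid = 10^seq(-3, 3, length.out = 25), folds = 10,
    var_quantile = 0.2, seed = 1L
  ), config$params %||% list())

  manifest <- list(package_version = as.character(utils::packageVersion("immunophen")),
                   parameters = p[setdiff(names(p), "lambda_grid")],
                   lambda_grid = range(p$lambda_grid),
                   inputs = list(), stages = list())
  note_input <- function(name, value) {
    manifest$inputs[[name]] <<- if (is.character(value) && length(value) == 1 &&
                                    file.exists(value)) {
      list(path = value, md5 = unname(tools::md5sum(value)))
    } else list(path = "in-memory")
  }

  results <- list()
  out_path <- function(f) file.path(config$output_dir, f)
  run_stage <- function(name, mandatory, fun) {
    status <- tryCatch({
      results[[name]] <<- fun()
      "ok"
    }, error = function(e) {
      if (mandatory) abort_ip("mandatory stage '", name, "' failed: ", conditionMessage(e))
      paste("failed:", conditionMessage(e))
    })
    manifest$stages[[name]] <<- status
  }

  # --- inputs ---------------------------------------------------------------
  note_input("expression", config$expression)
  expr <- if (is.character(config$expression)) {
    read_expression_matrix(config$expression, unit = config$unit %||% "TPM")
  } else config$expression
  if (identical(expr_unit(expr), "FPKM")) expr <- fpkm_to_tpm(expr)
  note_input("gene_sets", config$gene_sets)
  sets <- if (is.character(config$gene_sets)) read_gmt(config$gene_sets) else config$gene_sets

  # --- mandatory stages -----------------------------------------------------
  run_stage("enrich", TRUE, function() {
    enr <- ssgsea_scores(expr, sets, alpha = p$alpha)
    utils::write.table(as.data.frame(enr), out_path("enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    enr
  })
  run_stage("classify", TRUE, function() {
    lab <- classify_phenotypes(results$enrich, k = p$k)
    utils::write.csv(as.data.frame(lab), out_path("phenotypes.csv"),
                     row.names = FALSE, quote = FALSE)
    lab
  })

  # --- optional stages ------------------------------------------------------
  stromal_nm <- config$stromal_set %||% "stromal"
  immune_nm <- config$immune_set %||% "immune"
  if (all(c(stromal_nm, immune_nm) %in% names(sets))) {
    run_stage("estimate", FALSE, function() {
      est <- estimate_scores(expr, sets[[stromal_nm]], sets[[immune_nm]],
                             alpha = p$alpha)
      utils::write.table(est, out_path("estimate.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      est
    })
  }
  if (!is.null(config$signature_matrix)) {
    note_input("signature_matrix", config$signature_matrix)
    run_stage("deconvolve", FALSE, function() {
      sig <- if (is.character(config$signature_matrix)) {
        as_gene_matrix(read_expression_matrix(config$signature_matrix, unit = "COUNTS"))
      } else config$signature_matrix
      fr <- deconvolve(expr, sig)
      utils::write.table(as.data.frame(fr), out_path("fractions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      fr
    })
  }
  if (!is.null(config$maf)) {
    note_input("maf", config$maf)
    run_stage("genomics", FALSE, function() {
      maf <- if (is.character(config$maf)) read_maf(config$maf) else config$maf
      tmb <- compute_tmb(maf, samples = expr_samples(expr),
                         capture_size_mb = p$capture_size_mb)
      math <- math_by_sample(maf)
      g <- dplyr::left_join(tmb, math, by = "sample")
      utils::write.table(g, out_path("genomics.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      g
    })
  }
  if (!is.null(config$get_candidates)) {
    run_stage("get", FALSE, function() {
      der <- derive_get_signature(list(main = expr), config$get_candidates,
                                  anchor = config$get_anchor %||% "PDCD1",
                                  r_min = p$r_min, adj_p_max = p$adj_p_max)
      sig <- if (length(der$final_signature)) der$final_signature else
        config$get_candidates
      sc <- get_score(expr, sig, alpha = p$alpha)
      utils::write.csv(sc, out_path("get_scores.csv"), row.names = FALSE,
                       quote = FALSE)
      list(derivation = der, scores = sc)
    })
  }
  if (!is.null(config$clinical)) {
    note_input("clinical", config$clinical)
    run_stage("survival", FALSE, function() {
      clin <- if (is.character(config$clinical)) read_clinical(config$clinical)
        else validate_clinical(config$clinical)
      km <- km_logrank(clin, results$classify)
      tests <- dplyr::bind_rows(
        dplyr::mutate(km$overall, contrast = "overall"),
        if (!is.null(km$pairwise)) {
          dplyr::mutate(km$pairwise,
                        contrast = paste(.data$group1, "vs", .data$group2),
                        df = 1L)[c("statistic", "df", "p_value", "contrast")]
        }
      )
      utils::write.csv(tests, out_path("survival_tests.csv"),
                       row.names = FALSE, quote = FALSE)
      km
    })
  }
  if (!is.null(config$train_expression) && !is.null(config$train_ic50)) {
    note_input("train_expression", config$train_expression)
    run_stage("drugs", FALSE, function() {
      tr <- if (is.character(config$train_expression)) {
        read_expression_matrix(config$train_expression, unit = "COUNTS")
      } else config$train_expression
      ic <- if (is.character(config$train_ic50)) {
        utils::read.csv(config$train_ic50, stringsAsFactors = FALSE)
      } else config$train_ic50
      model <- train_ridge_model(tr, ic, lambda_grid = p$lambda_grid,
                                 folds = p$folds, var_quantile = p$var_quantile,
                                 seed = p$seed)
      pred <- predict_ic50(model, expr)
      cmp <- compare_response(pred, results$classify)
      utils::write.table(pred, out_path("drug_predictions.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      list(model = model, predictions = pred, comparison = cmp)
    })
  }

  jsonlite::write_json(manifest, out_path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
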