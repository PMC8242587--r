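#' Read a gene-by-sample expression table
#'
#' Expects a delimited text file whose first column holds gene identifiers and
#' whose header row names the samples. The delimiter is auto-detected between
#' tab and comma. Duplicate gene rows are collapsed by taking the per-sample
#' maximum (the usual probe-collapse rule; a warning reports how many rows were
#' merged). Duplicate sample names or non-numeric cells are errors.
#'
#' @param path Path to a TSV/CSV file.
#' @param unit Unit tag to attach, see [expression_matrix()].
#' @return An `immunophen_expr` tibble.
#' @export
read_expression_matrix <- function(path, unit = "TPM") {
  if (!file.exists(path)) abort_ip("file not found: ", path)
  if (file.size(path) == 0) abort_ip("empty expression file: ", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  if (nrow(raw) == 0) abort_ip("expression file has a header but no rows: ", path)
  samples <- names(raw)[-1]
  if (anyDuplicated(samples)) abort_ip("duplicate sample identifiers in header of ", path)
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      abort_ip("non-numeric value in sample '", samples[j], "', row ",
               if (is.na(bad_row)) "?" else bad_row, " of ", path)
    }
  }
  genes <- as.character(raw[[1]])
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    m <- as.matrix(raw[-1])
    agg <- stats::aggregate(as.data.frame(m), by = list(gene = genes), FUN = max)
    agg <- agg[match(unique(genes), agg$gene), , drop = FALSE]
    warning(n_dup, " duplicate gene row(s) collapsed by maximum", call. = FALSE)
    raw <- agg
    names(raw)[-1] <- samples
  }
  expression_matrix(tibble::as_tibble(raw), unit = unit)
}

#' Write an expression table as TSV
#' @param x An `immunophen_expr` tibble (or any gene-first table).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) abort_ip("empty file: ", path)
  if (grepl("\t", first)) "\t" else ","
}

#' Convert FPKM expression to TPM
#'
#' TPM for gene g in sample j is `FPKM_gj / sum_g(FPKM_gj) * 1e6`, so every
#' sample column sums to one million and within-sample gene ranks are
#' preserved exactly. Idempotent on TPM input.
#'
#' @param x An `immunophen_expr` tibble with unit `FPKM` (or `TPM`).
#' @return The rescaled table with unit `TPM`.
#' @examples
#' m <- expression_matrix(matrix(c(5, 5, 10), ncol = 1,
#'   dimnames = list(c("A", "B", "C"), "s1")), unit = "FPKM")
#' fpkm_to_tpm(m)
#' @export
fpkm_to_tpm <- function(x) {
  unit <- expr_unit(x)
  if (!unit %in% c("FPKM", "TPM")) {
    abort_ip("fpkm_to_tpm expects unit FPKM (or TPM), got ", unit)
  }
  m <- as_gene_matrix(x)
  cs <- colSums(m)
  if (any(cs <= 0)) {
    abort_ip("zero column sum in sample(s): ",
             paste(colnames(m)[cs <= 0], collapse = ", "))
  }
  expression_matrix(sweep(m, 2, cs, "/") * 1e6, unit = "TPM")
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then one or more genes, tab-separated.
#' Within-set duplicate genes are dropped with a warning; a repeated set name
#' or a line with fewer than three fields is an error.
#'
#' @param path Path to a `.gmt` file.
#' @return A named list of character vectors, with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_ip("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort_ip("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) abort_ip("GMT line ", short[1], " has fewer than 3 fields")
  nms <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nms)) {
    abort_ip("duplicate gene set name: ", nms[duplicated(nms)][1])
  }
  sets <- lapply(fields, function(f) {
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes within set '", f[[1]], "' dropped", call. = FALSE)
      genes <- unique(genes)
    }
    genes
  })
  names(sets) <- nms
  attr(sets, "descriptions") <- stats::setNames(vapply(fields, `[[`, character(1), 2L), nms)
  sets
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional per-set descriptions (recycled `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- attr(sets, "descriptions") %||% rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[[i]], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

maf_required_cols <- c(
  sample = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
  chromosome = "Chromosome", position = "Start_Position",
  variant_classification = "Variant_Classification",
  ref_count = "t_ref_count", alt_count = "t_alt_count"
)

#' Read a MAF-like mutation table
#'
#' Tab-separated with at least the standard MAF columns
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Chromosome`, `Start_Position`,
#' `Variant_Classification`, `t_ref_count`, `t_alt_count` (matched
#' case-insensitively; extra columns are ignored). Positions are 1-based.
#' Records with zero total depth are kept but flagged with a warning; they are
#' excluded from VAF-based statistics downstream.
#'
#' @param path Path to the MAF-like file.
#' @return A tibble with columns `sample`, `gene`, `chromosome`, `position`,
#'   `variant_classification`, `ref_count`, `alt_count`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) abort_ip("file not found: ", path)
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "#")
  hit <- match(tolower(maf_required_cols), tolower(names(raw)))
  if (anyNA(hit)) {
    abort_ip("MAF file missing required column(s): ",
             paste(maf_required_cols[is.na(hit)], collapse = ", "))
  }
  out <- tibble::as_tibble(raw[hit])
  names(out) <- names(maf_required_cols)
  out$sample <- as.character(out$sample)
  out$gene <- as.character(out$gene)
  out$chromosome <- as.character(out$chromosome)
  out$position <- as.integer(out$position)
  out$ref_count <- as.integer(out$ref_count)
  out$alt_count <- as.integer(out$alt_count)
  if (any(out$ref_count < 0 | out$alt_count < 0, na.rm = TRUE)) {
    abort_ip("negative read counts in MAF file")
  }
  zero <- out$ref_count + out$alt_count == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero read depth; excluded from VAF statistics",
            call. = FALSE)
  }
  out
}

#' Write a mutation table in MAF-like format
#' @param maf Tibble as returned by [read_maf()] or [simulate_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(maf, path) {
  out <- maf[names(maf_required_cols)]
  names(out) <- unname(maf_required_cols)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variant allele fractions of a mutation table
#'
#' `alt / (ref + alt)` per record; zero-depth records are dropped.
#' @param maf Mutation tibble.
#' @return The tibble restricted to depth > 0, with a `vaf` column.
#' @export
maf_vaf <- function(maf) {
  depth <- maf$ref_count + maf$alt_count
  out <- maf[depth > 0, , drop = FALSE]
  out$vaf <- out$alt_count / (out$ref_count + out$alt_count)
  out
}

#' Read a clinical table
#'
#' CSV or TSV with one row per sample; must contain `sample`, `time` and
#' `event` columns (case-insensitive). Times must be non-negative, events
#' binary 0/1 and sample identifiers unique. Character covariates become
#' factors with levels in first-seen file order.
#'
#' @param path Path to the file.
#' @return A validated tibble.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) abort_ip("file not found: ", path)
  sep <- detect_sep(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"")
  names(raw)[match(c("sample", "time", "event"), tolower(names(raw)))] <-
    c("sample", "time", "event")
  validate_clinical(tibble::as_tibble(raw))
}

validate_clinical <- function(x) {
  need <- setdiff(c("sample", "time", "event"), names(x))
  if (length(need)) abort_ip("clinical table missing column(s): ", paste(need, collapse = ", "))
  x$sample <- as.character(x$sample)
  if (anyDuplicated(x$sample)) abort_ip("duplicate sample identifiers in clinical table")
  if (!is.numeric(x$time) || any(!is.finite(x$time)) || any(x$time < 0)) {
    abort_ip("clinical 'time' must be finite and >= 0")
  }
  if (!all(x$event %in% c(0, 1))) abort_ip("clinical 'event' must be binary 0/1")
  x$event <- as.integer(x$event)
  for (nm in setdiff(names(x), c("sample", "time", "event"))) {
    if (is.character(x[[nm]])) x[[nm]] <- factor(x[[nm]], levels = unique(x[[nm]]))
  }
  x
}

#' Write a clinical table as CSV
#' @param clin Clinical tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clin, path) {
  utils::write.csv(as.data.frame(clin), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
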