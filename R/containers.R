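#' Build a gene-by-sample expression table
#'
#' The package's common currency is a tibble whose first column, `gene`, holds
#' unique gene identifiers and whose remaining columns hold one numeric vector
#' of expression values per sample. A `unit` attribute records the scale
#' (`"FPKM"`, `"TPM"`, `"COUNTS"` or `"LOG2_INTENSITY"`); values must be finite,
#' and non-negative unless the unit is `LOG2_INTENSITY`.
#'
#' @param x A numeric matrix with gene rownames and sample colnames, or a data
#'   frame whose first column holds gene identifiers.
#' @param unit Expression unit tag.
#' @return A tibble of class `immunophen_expr` with a `unit` attribute.
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' expression_matrix(m, unit = "TPM")
#' @export
expression_matrix <- function(x, unit = c("TPM", "FPKM", "COUNTS", "LOG2_INTENSITY")) {
  unit <- match.arg(toupper(unit[1]), c("TPM", "FPKM", "COUNTS", "LOG2_INTENSITY"))
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort_ip("expression matrix input needs gene rownames and sample colnames")
    }
    x <- tibble::as_tibble(x, rownames = "gene")
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort_ip("expression table needs a gene column and at least one sample")
  names(x)[1] <- "gene"
  x$gene <- as.character(x$gene)
  validate_expression(x, unit)
  attr(x, "unit") <- unit
  class(x) <- unique(c("immunophen_expr", class(x)))
  x
}

validate_expression <- function(x, unit) {
  if (anyDuplicated(x$gene)) {
    abort_ip("duplicate gene identifiers: ", paste(utils::head(unique(x$gene[duplicated(x$gene)]), 3), collapse = ", "))
  }
  samples <- names(x)[-1]
  if (anyDuplicated(samples)) abort_ip("duplicate sample identifiers in header")
  vals <- as.matrix(x[-1])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(x[-1], is.numeric, logical(1)))[1]
    abort_ip("non-numeric expression values in sample '", samples[bad], "'")
  }
  if (any(!is.finite(vals))) abort_ip("expression values must be finite (no NA/Inf)")
  if (unit != "LOG2_INTENSITY" && any(vals < 0)) {
    abort_ip("negative expression values are only valid for unit LOG2_INTENSITY")
  }
  invisible(x)
}

#' Extract the unit tag of an expression table
#' @param x An `immunophen_expr` tibble.
#' @return A string, or `NA` if untagged.
#' @export
expr_unit <- function(x) attr(x, "unit") %||% NA_character_

# numeric matrix view (genes x samples) of an expression/enrichment tibble
as_gene_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- as.character(x[[1]])
  storage.mode(m) <- "double"
  m
}

expr_samples <- function(x) names(x)[-1]

# enrichment tibble constructor (set x sample), used by the ssGSEA engine
enrichment_tbl <- function(scores, alpha, normalized = FALSE) {
  out <- tibble::as_tibble(scores, rownames = "set")
  attr(out, "alpha") <- alpha
  attr(out, "normalized") <- normalized
  class(out) <- unique(c("immunophen_enrich", class(out)))
  out
}

#' @export
print.immunophen_expr <- function(x, ...) {
  cat("# expression matrix: ", nrow(x), " genes x ", ncol(x) - 1L,
      " samples [", expr_unit(x), "]\n", sep = "")
  NextMethod()
}
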