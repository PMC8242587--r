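#' Heatmap of z-scored enrichment by sample
#'
#' @param enrich An `immunophen_enrich` tibble.
#' @param labels Optional phenotype tibble; samples are ordered by phenotype.
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(enrich, labels = NULL) {
  m <- as_gene_matrix(enrich)
  z <- t(scale(t(m)))
  long <- tibble::as_tibble(z, rownames = "set") |>
    tidyr::pivot_longer(-"set", names_to = "sample", values_to = "z")
  if (!is.null(labels)) {
    ord <- labels$sample[order(labels$phenotype)]
    long$sample <- factor(long$sample, levels = ord)
    long <- dplyr::left_join(long, labels[c("sample", "phenotype")],
                             by = "sample")
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$set,
                                     fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B") +
    ggplot2::labs(x = NULL, y = NULL, fill = "z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' PCA scatter of samples, optionally coloured by phenotype
#' @param pca Tibble from [pca_projection()].
#' @param labels Optional phenotype tibble.
#' @param dims Which two components to draw.
#' @return A ggplot object.
#' @export
plot_pca <- function(pca, labels = NULL, dims = c("PC1", "PC2")) {
  d <- pca
  if (!is.null(labels)) {
    d <- dplyr::left_join(d, labels[c("sample", "phenotype")], by = "sample")
  }
  aes <- if ("phenotype" %in% names(d)) {
    ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]],
                 colour = .data$phenotype)
  } else {
    ggplot2::aes(x = .data[[dims[1]]], y = .data[[dims[2]]])
  }
  ggplot2::ggplot(d, aes) + ggplot2::geom_point() + ggplot2::theme_minimal()
}

#' Kaplan-Meier step curves
#' @param x A `km_contrast` object.
#' @param ... Unused.
#' @return A ggplot object annotated with the overall log-rank p-value.
#' @export
plot_km <- function(x, ...) {
  start <- x$curves |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  d <- dplyr::bind_rows(start, x$curves[c("group", "time", "survival")])
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$survival,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival",
                  subtitle = sprintf("log-rank p = %.3g", x$overall$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.km_contrast <- function(object, ...) plot_km(object, ...)

#' Stacked bars of deconvolved cell fractions
#' @param fractions An `immunophen_fractions` tibble.
#' @return A ggplot object.
#' @export
plot_fractions <- function(fractions) {
  long <- tidyr::pivot_longer(fractions, -"cell_type", names_to = "sample",
                              values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$fraction,
                                     fill = .data$cell_type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' @export
autoplot.immunophen_fractions <- function(object, ...) plot_fractions(object)

#' Violin plot of a score by group
#' @param data Data frame holding the score and group columns.
#' @param score,group Tidy-eval column names.
#' @return A ggplot object.
#' @export
plot_score_violin <- function(data, score, group) {
  ggplot2::ggplot(data, ggplot2::aes(x = {{ group }}, y = {{ score }},
                                     fill = {{ group }})) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5, fill = "white") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
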