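#' Heatmap of a cell-line x tumor correlation matrix
#'
#' @param object A [spearman_matrix()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_matrix <- function(object, ...) {
  tidy.correlation_matrix(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$tumor, y = .data$cell_line, fill = .data$rho
    )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#2166ac", mid = "white", high = "#b2182b", midpoint = 0
    ) +
    ggplot2::labs(
      x = "primary tumor sample", y = "cell line",
      fill = "Spearman rho"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Volcano plot of a differential-expression table
#'
#' @param object A called `de_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_table <- function(object, ...) {
  df <- tidy.de_table(object)
  if (!"de" %in% colnames(df)) df$de <- FALSE
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lfc, y = -log10(.data$p_value), colour = .data$de
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b")) +
    ggplot2::labs(
      x = "log2 fold-change (tumor vs cell line)",
      y = "-log10 p", colour = "DE"
    ) +
    ggplot2::theme_minimal()
}

#' Bar plot of normalized enrichment scores
#'
#' @param object A [preranked_gsea()] results table.
#' @param q_cutoff Sets at or above this q are greyed out (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsea_results <- function(object, q_cutoff = 0.05, ...) {
  df <- as_tibble(unclass(object))
  df$significant <- df$q_value < q_cutoff
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$set, .data$nes), y = .data$nes,
    fill = .data$significant
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "normalized enrichment score",
      fill = sprintf("q < %g", q_cutoff)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of tumor purity against fidelity correlations
#'
#' Visualizes the confounding relationship the purity adjustment removes:
#' each point is one (cell line, tumor) pair.
#'
#' @param C A [spearman_matrix()] result.
#' @param purity Named purity vector or tibble (`sample_id`, `purity`).
#' @return A ggplot object.
#' @export
plot_purity_association <- function(C, purity) {
  pv <- purity_for_samples(purity, colnames(C))
  df <- tidy.correlation_matrix(C) |>
    dplyr::filter(.data$tumor %in% names(pv)) |>
    dplyr::mutate(purity = pv[.data$tumor])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$purity, y = .data$rho)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "#b2182b") +
    ggplot2::labs(x = "tumor purity", y = "cell line - tumor Spearman rho") +
    ggplot2::theme_minimal()
}

#' Fidelity distribution comparison of two panels
#'
#' @param panel_a,panel_b `panel_selection` tibbles.
#' @param names Length-2 labels for the panels.
#' @return A ggplot object (boxplots of per-cell-line median rho).
#' @export
plot_panel_comparison <- function(panel_a, panel_b,
                                  names = c("panel A", "panel B")) {
  df <- dplyr::bind_rows(
    dplyr::mutate(as_tibble(panel_a), panel = names[1]),
    dplyr::mutate(as_tibble(panel_b), panel = names[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$panel, y = .data$median_rho, fill = .data$panel
  )) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "median Spearman rho") +
    ggplot2::theme_minimal()
}
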