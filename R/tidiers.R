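#' Tidy a correlation matrix into long format
#'
#' @param x A [spearman_matrix()] result.
#' @param ... Unused.
#' @return Tibble (`cell_line`, `tumor`, `rho`).
#' @export
tidy.correlation_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "cell_line") |>
    tidyr::pivot_longer(-"cell_line", names_to = "tumor", values_to = "rho")
}

#' One-row summary of a correlation matrix
#'
#' @param x A [spearman_matrix()] result.
#' @param ... Unused.
#' @return Tibble (`n_cell_lines`, `n_tumors`, `n_genes`, `median_rho`,
#'   `min_rho`, `max_rho`).
#' @export
glance.correlation_matrix <- function(x, ...) {
  tibble(
    n_cell_lines = nrow(x), n_tumors = ncol(x),
    n_genes = length(attr(x, "genes")),
    median_rho = median(x, na.rm = TRUE),
    min_rho = min(x, na.rm = TRUE), max_rho = max(x, na.rm = TRUE)
  )
}

#' Tidy a differential-expression table
#'
#' Already tibble-shaped; returned without the class decoration.
#'
#' @param x A `de_table`.
#' @param ... Unused.
#' @return Plain tibble.
#' @export
tidy.de_table <- function(x, ...) {
  as_tibble(unclass(x))
}

#' One-row summary of a differential-expression table
#'
#' @param x A `de_table` (after [call_de()] if call counts are wanted).
#' @param ... Unused.
#' @return Tibble with gene counts and the variance-prior parameters.
#' @export
glance.de_table <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_de = if ("de" %in% colnames(x)) sum(x$de) else NA_integer_,
    n_up = if (all(c("de", "lfc") %in% colnames(x))) {
      sum(x$de & x$lfc > 0)
    } else {
      NA_integer_
    },
    n_down = if (all(c("de", "lfc") %in% colnames(x))) {
      sum(x$de & x$lfc < 0)
    } else {
      NA_integer_
    },
    d0 = attr(x, "d0") %||% NA_real_,
    s02 = attr(x, "s02") %||% NA_real_,
    df_residual = attr(x, "df_residual") %||% NA_real_
  )
}

#' One-row summary of a fidelity analysis
#'
#' @param x An [analyze_cohort()] result.
#' @param ... Unused.
#' @return Tibble with the confounding diagnostics and scale of the run.
#' @export
glance.fidelity_analysis <- function(x, ...) {
  tibble(
    n_cell_lines = nrow(x$correlations),
    n_tumors = ncol(x$correlations),
    n_genes_used = length(x$variable_genes),
    n_genes_removed = if (is.null(x$purity_filter)) {
      0L
    } else {
      sum(x$purity_filter$removed)
    },
    purity_adjusted = x$adjusted,
    association_r = x$association$r,
    association_p = x$association$p_value,
    quartile_p = x$quartile_test$p_value,
    quartile_stars = x$quartile_test$stars
  )
}

#' One-row summary of a subtype analysis
#'
#' @param x A [classify_subtypes()] result.
#' @param ... Unused.
#' @return Tibble with accuracy, gate state and call counts.
#' @export
glance.subtype_analysis <- function(x, ...) {
  cl <- x$cell_line_calls
  tibble(
    n_template_genes = sum(lengths(x$templates$templates)),
    n_subtypes = length(x$templates$templates),
    test_accuracy = x$accuracy$accuracy,
    gate_passed = x$accuracy$gate_passed,
    n_cell_lines_assigned = if (is.null(cl)) NA_integer_ else sum(cl$assigned),
    n_cell_lines_unassigned = if (is.null(cl)) {
      NA_integer_
    } else {
      sum(!cl$assigned)
    }
  )
}
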