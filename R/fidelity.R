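#' Select the most variable genes by interquartile range
#'
#' Ranks genes by IQR across the (tumor) samples, descending, ties broken
#' lexicographically by gene ID so the selection is deterministic.
#'
#' @param tumor_x Log-scale genes x tumor-samples matrix.
#' @param n Number of genes to keep (default 5000).
#' @return Character vector of gene IDs, most variable first.
#' @export
select_variable_genes <- function(tumor_x, n = 5000) {
  check_expression_matrix(tumor_x, "tumor_x")
  if (n < 1) abort("`n` must be >= 1.")
  iqr <- apply(tumor_x, 1, function(v) {
    q <- quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
  if (n > length(iqr)) {
    warn(sprintf(
      "requested %d genes but only %d available; returning all.", n, length(iqr)
    ))
    n <- length(iqr)
  }
  ord <- order(-iqr, rownames(tumor_x))
  rownames(tumor_x)[ord][seq_len(n)]
}

#' Cell-line x tumor Spearman correlation matrix
#'
#' Spearman rho (average-rank tie handling) between every cell line and
#' every tumor sample over a fixed gene list — the per-pair fidelity scores.
#'
#' @param cell_x,tumor_x Log-scale genes x samples matrices.
#' @param genes Gene IDs to correlate over (must be present in both).
#' @param tumor_type Optional context label stored with the result.
#' @return Cell-line x tumor matrix of class `correlation_matrix` with
#'   attributes `genes` and `tumor_type`. Samples with zero variance over
#'   the gene list yield `NA` entries with a warning.
#' @export
spearman_matrix <- function(cell_x, tumor_x, genes, tumor_type = NA_character_) {
  check_expression_matrix(cell_x, "cell_x")
  check_expression_matrix(tumor_x, "tumor_x")
  missing <- setdiff(genes, intersect(rownames(cell_x), rownames(tumor_x)))
  if (length(missing)) {
    abort(sprintf(
      "%d gene(s) absent from one of the matrices (e.g. %s).",
      length(missing), missing[1]
    ))
  }
  a <- cell_x[genes, , drop = FALSE]
  b <- tumor_x[genes, , drop = FALSE]
  flat_cells <- colnames(a)[apply(a, 2, sd) == 0]
  flat_tumors <- colnames(b)[apply(b, 2, sd) == 0]
  if (length(flat_cells) || length(flat_tumors)) {
    warn(sprintf(
      "zero-variance sample(s) over the gene list: %s",
      paste(c(flat_cells, flat_tumors), collapse = ", ")
    ))
  }
  rho <- suppressWarnings(cor(a, b, method = "spearman"))
  if (length(flat_cells)) rho[flat_cells, ] <- NA_real_
  if (length(flat_tumors)) rho[, flat_tumors] <- NA_real_
  structure(rho,
    class = c("correlation_matrix", "matrix", "array"),
    genes = genes, tumor_type = tumor_type
  )
}

#' Per-cell-line fidelity summary
#'
#' Median and SD of each cell line's correlations with the tumor cohort,
#' plus the rank among cell lines (by median, descending; ties broken by
#' cell-line ID so ranks are a permutation of 1..n).
#'
#' @param C A [spearman_matrix()] result (cell lines as rows).
#' @return Tibble (`cell_line`, `median_rho`, `sd_rho`, `rank`).
#' @export
summarize_cell_lines <- function(C) {
  if (!is.matrix(C) || nrow(C) == 0) abort("`C` must be a non-empty matrix.")
  out <- tibble(
    cell_line = rownames(C),
    median_rho = unname(apply(C, 1, median, na.rm = TRUE)),
    sd_rho = unname(apply(C, 1, sd, na.rm = TRUE))
  )
  ord <- order(-out$median_rho, out$cell_line)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  tt <- attr(C, "tumor_type")
  if (!is.null(tt) && !is.na(tt)) out$tumor_type <- tt
  dplyr::arrange(out, .data$rank)
}

#' Cross-tumor-type median correlation matrix
#'
#' Entry (i, j) is the median rho between cell lines of type i and tumors of
#' type j; a dendrogram order (average-linkage hierarchical clustering on
#' Euclidean row distances) gives a deterministic display order, and for
#' each tumor type the best-matching cell-line type is reported.
#'
#' @param C Correlation matrix covering all cell lines (rows) and tumors
#'   (columns).
#' @param cell_line_types Character vector of tumor-type labels per row.
#' @param tumor_types Character vector of tumor-type labels per column.
#' @return List with `medians` (type x type matrix), `row_order` (display
#'   order of cell-line types) and `best_match` tibble
#'   (`tumor_type`, `best_cell_line_type`, `median_rho`, `self_best`).
#' @export
cross_type_median_matrix <- function(C, cell_line_types, tumor_types) {
  if (length(cell_line_types) != nrow(C) || length(tumor_types) != ncol(C)) {
    abort("type labels must match the matrix dimensions.")
  }
  rl <- sort(unique(cell_line_types))
  cl <- sort(unique(tumor_types))
  med <- matrix(NA_real_, length(rl), length(cl), dimnames = list(rl, cl))
  for (i in rl) {
    for (j in cl) {
      med[i, j] <- median(C[cell_line_types == i, tumor_types == j],
        na.rm = TRUE
      )
    }
  }
  row_order <- if (nrow(med) > 2) {
    rl[hclust(dist(med), method = "average")$order]
  } else {
    rl
  }
  best <- tibble(
    tumor_type = cl,
    best_cell_line_type = rl[apply(med, 2, which.max)],
    median_rho = apply(med, 2, max)
  )
  best$self_best <- best$tumor_type == best$best_cell_line_type
  list(medians = med, row_order = row_order, best_match = best)
}

#' Purity-quartile fidelity diagnostic
#'
#' Compares the fidelity correlations against top-quartile-purity tumors
#' with those against bottom-quartile tumors by a one-sided Wilcoxon
#' rank-sum test (top > bottom). Quartile membership uses the type-7
#' percentile convention; tumors exactly on a boundary fall in the middle
#' group and are excluded from both extremes. Exact enumeration is used for
#' group sizes up to 20 (without ties), the tie-corrected normal
#' approximation otherwise.
#'
#' @param C A [spearman_matrix()] result.
#' @param purity Named numeric vector or tibble (`sample_id`, `purity`)
#'   covering the tumor columns.
#' @return Tibble (`n_top`, `n_bottom`, `statistic`, `p_value`, `stars`).
#' @export
purity_quartile_test <- function(C, purity) {
  pv <- purity_for_samples(purity, colnames(C))
  if (length(pv) < 4) abort("need >= 4 tumors with purity.")
  if (sd(pv) == 0) abort("purity has zero variance.")
  q <- quantile(pv, c(0.25, 0.75), type = 7, names = FALSE)
  top <- names(pv)[pv > q[2]]
  bottom <- names(pv)[pv < q[1]]
  x <- as.vector(C[, top, drop = FALSE])
  y <- as.vector(C[, bottom, drop = FALSE])
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  exact <- min(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact, correct = TRUE)
  )
  tibble(
    n_top = length(top), n_bottom = length(bottom),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    stars = p_stars(wt$p.value)
  )
}

#' Association between tumor purity and fidelity correlations
#'
#' Pearson correlation between every (cell line, tumor) fidelity rho and
#' that tumor's purity, over all pairs — the confounding diagnostic that
#' should collapse to ~0 after purity adjustment.
#'
#' @inheritParams purity_quartile_test
#' @return Tibble (`r`, `p_value`, `n_pairs`).
#' @export
purity_correlation_association <- function(C, purity) {
  pv <- purity_for_samples(purity, colnames(C))
  if (sd(pv) == 0) abort("purity has zero variance.")
  Csub <- C[, names(pv), drop = FALSE]
  rho <- as.vector(Csub)
  pur <- rep(pv, each = nrow(Csub))
  ok <- !is.na(rho)
  ct <- cor.test(rho[ok], pur[ok], method = "pearson")
  tibble(
    r = unname(ct$estimate), p_value = ct$p.value, n_pairs = sum(ok)
  )
}
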