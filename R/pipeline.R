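#' Run the fidelity-correlation workflow on one cohort
#'
#' The per-tumor-type analysis chain: upper-quartile normalization, log2
#' transform, optional batch correction of the tumor samples, optional
#' purity adjustment (purity-correlated gene removal followed by
#' regression to the purity-1 reference), variable-gene selection on
#' tumors only, the cell-line x tumor Spearman matrix, per-cell-line
#' summaries, and the two purity-confounding diagnostics.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Metadata tibble (`sample_id`, `cohort`, `purity`,
#'   `batch`).
#' @param config A [pipeline_config()].
#' @param adjust_purity Apply the purity filter + regression (default
#'   `TRUE`).
#' @param batch_correct Apply [combat_adjust()] to tumor samples when more
#'   than one batch is present (default `TRUE`).
#' @return List of class `fidelity_analysis`: `correlations`
#'   (`correlation_matrix`), `cell_line_summary`, `variable_genes`,
#'   `purity_filter` (tibble or `NULL`), `quartile_test`, `association`,
#'   `config`, `adjusted` flag.
#' @export
analyze_cohort <- function(counts, samples, config = pipeline_config(),
                           adjust_purity = TRUE, batch_correct = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!all(colnames(counts) == samples$sample_id)) {
    samples <- samples[match(colnames(counts), samples$sample_id), ]
  }
  tumors <- samples$sample_id[samples$cohort == "tumor"]
  cells <- samples$sample_id[samples$cohort == "cell_line"]
  if (!length(tumors) || !length(cells)) {
    abort("need both tumor and cell_line samples.")
  }
  norm <- log_transform(upper_quartile_normalize(counts))
  tumor_x <- norm[, tumors, drop = FALSE]
  cell_x <- norm[, cells, drop = FALSE]

  if (batch_correct) {
    batch <- samples$batch[match(tumors, samples$sample_id)]
    if (length(unique(batch)) > 1) {
      tumor_x <- combat_adjust(tumor_x, batch)
    }
  }

  purity <- setNames(
    samples$purity[match(tumors, samples$sample_id)], tumors
  )
  purity_filter <- NULL
  if (adjust_purity) {
    purity_filter <- purity_gene_filter(
      tumor_x, purity,
      r_cutoff = config$purity_r_cutoff,
      fdr_cutoff = config$purity_fdr_cutoff,
      mode = config$purity_filter_mode
    )
    keep <- purity_filter$gene[!purity_filter$removed]
    tumor_x <- regress_out_purity(tumor_x[keep, , drop = FALSE], purity)
    cell_x <- cell_x[keep, , drop = FALSE]
  }

  genes <- select_variable_genes(tumor_x, n = min(
    config$n_variable_genes, nrow(tumor_x)
  ))
  C <- spearman_matrix(cell_x, tumor_x, genes)
  structure(
    list(
      correlations = C,
      cell_line_summary = summarize_cell_lines(C),
      variable_genes = genes,
      purity_filter = purity_filter,
      quartile_test = purity_quartile_test(C, purity),
      association = purity_correlation_association(C, purity),
      config = config,
      adjusted = adjust_purity
    ),
    class = "fidelity_analysis"
  )
}

#' Run the subtype-classification workflow on one cohort
#'
#' The modified nearest-template workflow: stratified 80/20 split of the
#' tumors, one-vs-rest template derivation on the training set, cell-line
#' relevance filtering (tumor-vs-cell-line DE and top-half expression
#' rules), nearest-template classification of the held-out test tumors,
#' the accuracy gate, and — when the gate passes — classification of the
#' cell lines.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Metadata tibble (`sample_id`, `cohort`, `purity`,
#'   `subtype` for tumors).
#' @param config A [pipeline_config()].
#' @return List of class `subtype_analysis`: `templates` (filtered),
#'   `split`, `test_calls`, `accuracy`, `cell_line_calls` (`NULL` when the
#'   gate fails), `tumor_vs_cl_de`.
#' @export
classify_subtypes <- function(counts, samples, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!all(colnames(counts) == samples$sample_id)) {
    samples <- samples[match(colnames(counts), samples$sample_id), ]
  }
  tumors <- samples[samples$cohort == "tumor", ]
  cells <- samples[samples$cohort == "cell_line", ]
  if (anyNA(tumors$subtype)) abort("every tumor needs a subtype label.")

  norm <- log_transform(upper_quartile_normalize(counts))
  split <- split_train_test(tumors$sample_id, tumors$subtype,
    train_frac = config$train_frac, seed = config$seed
  )
  train_labels <- tumors$subtype[match(split$train, tumors$sample_id)]
  templates <- build_templates(
    norm[, split$train, drop = FALSE], train_labels,
    lfc_cutoff = config$template_lfc_cutoff,
    fdr_cutoff = config$template_fdr_cutoff
  )
  tumor_vs_cl <- differential_expression(counts, samples,
    purity_covariate = !anyNA(tumors$purity),
    lfc_cutoff = config$de_lfc_cutoff, fdr_cutoff = config$de_fdr_cutoff
  )
  templates <- filter_templates_for_cell_lines(
    templates, tumor_vs_cl, norm[, cells$sample_id, drop = FALSE],
    cl_de_cutoff = config$template_cl_de_cutoff
  )
  test_calls <- ntp_classify(
    norm[, split$test, drop = FALSE], templates,
    n_resample = config$n_resample, seed = config$seed,
    fdr_cutoff = config$ntp_fdr_cutoff
  )
  truth <- setNames(tumors$subtype, tumors$sample_id)
  accuracy <- evaluate_accuracy(test_calls, truth, gate = config$accuracy_gate)
  cell_line_calls <- NULL
  if (accuracy$gate_passed) {
    cell_line_calls <- ntp_classify(
      norm[, cells$sample_id, drop = FALSE], templates,
      n_resample = config$n_resample, seed = config$seed,
      fdr_cutoff = config$ntp_fdr_cutoff
    )
  }
  structure(
    list(
      templates = templates, split = split, test_calls = test_calls,
      accuracy = accuracy, cell_line_calls = cell_line_calls,
      tumor_vs_cl_de = tumor_vs_cl
    ),
    class = "subtype_analysis"
  )
}
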