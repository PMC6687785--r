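#' Pipeline thresholds and seeds
#'
#' Central container for every tunable cutoff in the workflow. Defaults are
#' the published analysis values: purity filter R <= -0.4 at FDR < 0.01,
#' differential expression |LFC| > 2 at FDR < 0.01, subtype template genes
#' LFC > 1 at FDR < 0.01, 5000 variable genes, subtype-call FDR cutoff 0.05,
#' test-set accuracy gate 0.80, and 5 cell lines per tumor type in the
#' representative panel.
#'
#' @param purity_r_cutoff Gene-purity correlation removal threshold
#'   (genes with R at or below it, and significant, are removed).
#' @param purity_fdr_cutoff BH-FDR cutoff for the purity filter.
#' @param purity_filter_mode `"negative"` (default; removes only negatively
#'   correlated genes, the contamination direction) or `"two_sided"`.
#' @param de_lfc_cutoff,de_fdr_cutoff Differential-expression call cutoffs.
#' @param template_lfc_cutoff,template_fdr_cutoff Subtype template gene
#'   cutoffs (one-vs-rest).
#' @param template_cl_de_cutoff Absolute tumor-vs-cell-line LFC above which a
#'   template gene is removed as cell-line irrelevant.
#' @param n_variable_genes Number of most-variable (IQR-ranked) genes used
#'   for correlation.
#' @param ntp_fdr_cutoff Subtype-call FDR above which a sample is unassigned.
#' @param accuracy_gate Minimum test-set accuracy before classifying cell
#'   lines.
#' @param panel_size Cell lines per tumor type in the representative panel.
#' @param train_frac Training fraction of the subtype split.
#' @param n_resample NTP resampling iterations.
#' @param n_perm Preranked-enrichment permutations.
#' @param seed Integer seed recorded with results.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(purity_r_cutoff = -0.4,
                            purity_fdr_cutoff = 0.01,
                            purity_filter_mode = c("negative", "two_sided"),
                            de_lfc_cutoff = 2,
                            de_fdr_cutoff = 0.01,
                            template_lfc_cutoff = 1,
                            template_fdr_cutoff = 0.01,
                            template_cl_de_cutoff = 2,
                            n_variable_genes = 5000,
                            ntp_fdr_cutoff = 0.05,
                            accuracy_gate = 0.80,
                            panel_size = 5,
                            train_frac = 0.8,
                            n_resample = 1000,
                            n_perm = 1000,
                            seed = 1L) {
  purity_filter_mode <- match.arg(purity_filter_mode)
  cfg <- list(
    purity_r_cutoff = purity_r_cutoff,
    purity_fdr_cutoff = purity_fdr_cutoff,
    purity_filter_mode = purity_filter_mode,
    de_lfc_cutoff = de_lfc_cutoff, de_fdr_cutoff = de_fdr_cutoff,
    template_lfc_cutoff = template_lfc_cutoff,
    template_fdr_cutoff = template_fdr_cutoff,
    template_cl_de_cutoff = template_cl_de_cutoff,
    n_variable_genes = n_variable_genes,
    ntp_fdr_cutoff = ntp_fdr_cutoff,
    accuracy_gate = accuracy_gate, panel_size = panel_size,
    train_frac = train_frac, n_resample = n_resample, n_perm = n_perm,
    seed = as.integer(seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  in01 <- c(
    "purity_fdr_cutoff", "de_fdr_cutoff", "template_fdr_cutoff",
    "ntp_fdr_cutoff", "accuracy_gate", "train_frac"
  )
  for (nm in in01) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort(sprintf("`%s` must be a single value in (0, 1].", nm))
    }
  }
  if (cfg$purity_r_cutoff < -1 || cfg$purity_r_cutoff > 1) {
    abort("`purity_r_cutoff` must lie in [-1, 1].")
  }
  pos <- c(
    "de_lfc_cutoff", "template_lfc_cutoff", "template_cl_de_cutoff",
    "n_variable_genes", "panel_size", "n_resample", "n_perm"
  )
  for (nm in pos) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0) {
      abort(sprintf("`%s` must be a single positive value.", nm))
    }
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Keys override the defaults of [pipeline_config()]; unknown keys are an
#' error so threshold typos cannot pass silently.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort(sprintf(
      "unknown configuration key(s): %s", paste(unknown, collapse = ", ")
    ))
  }
  do.call(pipeline_config, vals)
}
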