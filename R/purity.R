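#' Average two tumor-purity estimates
#'
#' Arithmetic mean where both estimates are present; where only one source
#' covers a sample its value is used and a warning records the fallback.
#'
#' @param p1,p2 Tibbles with columns `sample_id` and `purity` (a named
#'   numeric vector is also accepted).
#' @return Tibble (`sample_id`, `purity`, `source`) with source `"averaged"`.
#' @export
average_purity <- function(p1, p2) {
  p1 <- as_purity_tbl(p1, "p1")
  p2 <- as_purity_tbl(p2, "p2")
  if (nrow(p1) && nrow(p2) && !length(intersect(p1$sample_id, p2$sample_id))) {
    abort("purity vectors share no sample IDs.")
  }
  merged <- dplyr::full_join(
    dplyr::rename(p1, purity1 = "purity"),
    dplyr::rename(p2, purity2 = "purity"),
    by = "sample_id"
  )
  one_sided <- sum(is.na(merged$purity1) | is.na(merged$purity2))
  if (one_sided > 0) {
    warn(sprintf(
      "%d sample(s) present in only one source; using the available value.",
      one_sided
    ))
  }
  merged |>
    dplyr::mutate(
      purity = rowMeans(cbind(.data$purity1, .data$purity2), na.rm = TRUE),
      source = "averaged"
    ) |>
    dplyr::select("sample_id", "purity", "source")
}

as_purity_tbl <- function(p, arg) {
  if (is.numeric(p) && !is.null(names(p))) {
    p <- tibble(sample_id = names(p), purity = unname(p))
  }
  if (!is.data.frame(p) || !all(c("sample_id", "purity") %in% colnames(p))) {
    abort(sprintf("`%s` must have columns sample_id and purity.", arg))
  }
  bad <- p$purity < 0 | p$purity > 1
  if (any(bad, na.rm = TRUE)) {
    abort(sprintf("`%s` has purity values outside [0, 1].", arg))
  }
  as_tibble(p[!is.na(p$purity), c("sample_id", "purity")])
}

#' Signature-score purity estimate
#'
#' A simplified purity proxy for synthetic or signature-annotated data: the
#' per-sample mean z-score over immune plus stromal signature genes
#' (contamination enrichment), mapped affinely to a purity scale so the
#' highest-scoring (most contaminated) sample receives `purity_range[1]` and
#' the lowest-scoring sample `purity_range[2]`.
#'
#' @param x Log-scale genes x samples matrix (tumors).
#' @param immune_set,stromal_set Character vectors of signature genes; each
#'   must overlap `x` by at least 5 genes (`stromal_set` may be `NULL` to
#'   use a single combined signature).
#' @param purity_range Length-2 numeric, the purity assigned to the most /
#'   least contaminated sample.
#' @return Tibble (`sample_id`, `purity`, `score`, `source = "signature"`).
#' @export
signature_purity_estimate <- function(x, immune_set, stromal_set = NULL,
                                      purity_range = c(0.1, 1)) {
  check_expression_matrix(x)
  sets <- list(immune = immune_set)
  if (!is.null(stromal_set)) sets$stromal <- stromal_set
  for (nm in names(sets)) {
    present <- intersect(sets[[nm]], rownames(x))
    if (length(present) < 5) {
      abort(sprintf("fewer than 5 %s signature genes present in the matrix.", nm))
    }
    sets[[nm]] <- present
  }
  genes <- unique(unlist(sets))
  sub <- x[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  sds[sds == 0] <- 1
  z <- (sub - rowMeans(sub)) / sds
  score <- colMeans(z)
  rng <- range(score)
  purity <- if (diff(rng) == 0) {
    rep(mean(purity_range), length(score))
  } else {
    # affine, decreasing: high contamination score -> low purity
    purity_range[2] + (score - rng[1]) / diff(rng) *
      (purity_range[1] - purity_range[2])
  }
  tibble(
    sample_id = colnames(x), purity = unname(purity),
    score = unname(score), source = "signature"
  )
}

#' Flag genes correlated with tumor purity
#'
#' Per-gene Pearson correlation of log-expression with purity across tumors,
#' BH-adjusted over all genes. Under the default `"negative"` mode a gene is
#' removed when R <= `r_cutoff` and adjusted p < `fdr_cutoff` — the
#' immune/stromal contamination direction; `"two_sided"` removes strong
#' correlations of either sign.
#'
#' @param tumor_x Log-scale genes x tumors matrix.
#' @param purity Named numeric vector or tibble (`sample_id`, `purity`)
#'   covering the columns of `tumor_x`.
#' @param r_cutoff Correlation threshold (default -0.4).
#' @param fdr_cutoff BH-FDR cutoff (default 0.01).
#' @param mode `"negative"` (default) or `"two_sided"`.
#' @return Tibble (`gene`, `r`, `p_value`, `adj_p_value`, `removed`).
#' @export
purity_gene_filter <- function(tumor_x, purity, r_cutoff = -0.4,
                               fdr_cutoff = 0.01,
                               mode = c("negative", "two_sided")) {
  mode <- match.arg(mode)
  check_expression_matrix(tumor_x, "tumor_x")
  pv <- purity_for_samples(purity, colnames(tumor_x))
  if (length(pv) < 10) abort("need >= 10 tumors with purity.")
  if (sd(pv) == 0) abort("purity has zero variance.")
  x <- tumor_x[, names(pv), drop = FALSE]
  r <- as.vector(cor(t(x), pv))
  df <- length(pv) - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  # constant genes have undefined correlation; they carry no purity signal
  r[is.na(r)] <- 0
  p[is.na(p)] <- 1
  adj <- p.adjust(p, method = "BH")
  removed <- if (mode == "negative") {
    r <= r_cutoff & adj < fdr_cutoff
  } else {
    abs(r) >= abs(r_cutoff) & adj < fdr_cutoff
  }
  tibble(
    gene = rownames(tumor_x), r = r, p_value = p,
    adj_p_value = adj, removed = removed
  )
}

#' Project tumor expression to a pure-tumor reference
#'
#' Per gene, ordinary least squares of log-expression on purity across the
#' tumor samples; the adjusted value is the fitted value at purity = 1 plus
#' the sample's residual. This removes the linear contamination trend while
#' leaving residual variation untouched, and places tumors on the same
#' purity-1 scale as cell lines.
#'
#' @inheritParams purity_gene_filter
#' @return Adjusted matrix of the same shape as `tumor_x`.
#' @export
regress_out_purity <- function(tumor_x, purity) {
  check_expression_matrix(tumor_x, "tumor_x")
  pv <- purity_for_samples(purity, colnames(tumor_x))
  if (length(pv) < 3) abort("need >= 3 tumors to regress out purity.")
  if (sd(pv) == 0) abort("purity has zero variance.")
  x <- tumor_x[, names(pv), drop = FALSE]
  pc <- pv - mean(pv)
  slope <- as.vector(((x - rowMeans(x)) %*% pc) / sum(pc^2))
  adjusted <- x - outer(slope, pv - 1)
  out <- tumor_x
  out[, names(pv)] <- adjusted
  attr(out, "provenance") <- attr(tumor_x, "provenance")
  add_provenance(out, "purity_adjusted")
}

purity_for_samples <- function(purity, sample_ids) {
  if (is.data.frame(purity)) {
    purity <- setNames(purity$purity, purity$sample_id)
  }
  if (is.null(names(purity))) abort("`purity` must be named by sample ID.")
  purity <- purity[!is.na(purity)]
  common <- intersect(sample_ids, names(purity))
  if (!length(common)) abort("no overlap between purity names and samples.")
  purity[common]
}
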