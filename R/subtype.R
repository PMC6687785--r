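#' Stratified train/test split
#'
#' Splits samples into training and test partitions stratified by subtype;
#' every subtype appears in both partitions (training counts are rounded,
#' then clamped so neither side is empty).
#'
#' @param sample_ids Character vector of sample IDs.
#' @param labels Subtype label per sample.
#' @param train_frac Training fraction (default 0.8).
#' @param seed Seed for the random allocation.
#' @return List with `train` and `test` character vectors.
#' @export
split_train_test <- function(sample_ids, labels, train_frac = 0.8, seed = 1L) {
  if (length(sample_ids) != length(labels)) {
    abort("`labels` must match `sample_ids` in length.")
  }
  tab <- table(labels)
  if (any(tab < 2)) {
    abort(sprintf(
      "subtype(s) with a single sample: %s",
      paste(names(tab)[tab < 2], collapse = ", ")
    ))
  }
  withr::with_seed(seed, {
    train <- character()
    for (s in sort(unique(labels))) {
      ids <- sample_ids[labels == s]
      n_train <- min(max(round(train_frac * length(ids)), 1), length(ids) - 1)
      train <- c(train, sample(ids, n_train))
    }
    list(train = sort(train), test = sort(setdiff(sample_ids, train)))
  })
}

#' Derive subtype marker templates from training tumors
#'
#' One-vs-rest moderated-t differential expression per subtype on the
#' (log-scale) training matrix; template genes are those up-regulated in
#' the subtype with LFC above `lfc_cutoff` and BH-FDR below `fdr_cutoff`.
#' A gene qualifying for several subtypes is assigned to the subtype where
#' its LFC is largest, keeping the templates disjoint.
#'
#' @param train_x Log-scale genes x training-samples matrix.
#' @param labels Subtype label per training sample.
#' @param lfc_cutoff,fdr_cutoff Template cutoffs (defaults 1 and 0.01).
#' @return List of class `subtype_templates`: `templates` (named list of
#'   marker-gene vectors), `provenance` tibble
#'   (`gene`, `subtype`, `lfc`, `fdr`, `status`), `params`.
#' @export
build_templates <- function(train_x, labels, lfc_cutoff = 1,
                            fdr_cutoff = 0.01) {
  check_expression_matrix(train_x, "train_x")
  if (length(labels) != ncol(train_x)) {
    abort("`labels` must match the training columns.")
  }
  subtypes <- sort(unique(labels))
  if (length(subtypes) < 2) abort("need >= 2 subtypes.")
  hits <- list()
  for (s in subtypes) {
    design <- cbind(intercept = 1, group = as.numeric(labels == s))
    fit <- fit_weighted_lm(train_x, weights = NULL, design = design)
    tab <- ebayes_moderate(fit, coef = "group")
    sel <- tab$lfc > lfc_cutoff & tab$fdr < fdr_cutoff
    hits[[s]] <- tibble(
      gene = tab$gene[sel], subtype = s,
      lfc = tab$lfc[sel], fdr = tab$fdr[sel]
    )
  }
  prov <- dplyr::bind_rows(hits)
  if (!nrow(prov)) prov$status <- character(0)
  if (nrow(prov)) {
    # disjointness: a multiply-qualifying gene goes to its max-LFC subtype
    prov <- prov |>
      dplyr::group_by(.data$gene) |>
      dplyr::mutate(
        status = ifelse(seq_along(.data$lfc) == which.max(.data$lfc),
          "kept", "dropped_multi_subtype"
        )
      ) |>
      dplyr::ungroup()
  }
  templates <- lapply(subtypes, function(s) {
    sort(prov$gene[prov$subtype == s & prov$status == "kept"])
  })
  names(templates) <- subtypes
  empty <- names(templates)[lengths(templates) == 0]
  if (length(empty)) {
    abort(sprintf(
      "no template genes for subtype(s) %s; lower cutoffs or inspect data.",
      paste(empty, collapse = ", ")
    ))
  }
  structure(
    list(
      templates = templates, provenance = prov,
      params = list(lfc_cutoff = lfc_cutoff, fdr_cutoff = fdr_cutoff)
    ),
    class = "subtype_templates"
  )
}

#' Filter template genes for cell-line relevance
#'
#' Removes template genes that (a) are strongly differential between
#' tumors and cell lines (|LFC| above `cl_de_cutoff` in `tumor_vs_cl_de`),
#' or (b) are not in the top 50% of expression in at least `min_cell_lines`
#' cell lines — i.e. at or above the sample's median expression across all
#' genes. Dropped genes are recorded with a provenance flag.
#'
#' @param templates A [build_templates()] result.
#' @param tumor_vs_cl_de A `de_table` for the tumor-vs-cell-line contrast
#'   covering the template genes.
#' @param cell_x Log-scale genes x cell-line matrix.
#' @param cl_de_cutoff Absolute LFC removal cutoff (default 2).
#' @param min_cell_lines Minimum cell lines in which a gene must reach the
#'   top half of expression (default 2).
#' @return A filtered `subtype_templates` with updated provenance.
#' @export
filter_templates_for_cell_lines <- function(templates, tumor_vs_cl_de,
                                            cell_x, cl_de_cutoff = 2,
                                            min_cell_lines = 2) {
  stopifnot(inherits(templates, "subtype_templates"))
  check_expression_matrix(cell_x, "cell_x")
  all_genes <- unlist(templates$templates)
  missing_de <- setdiff(all_genes, tumor_vs_cl_de$gene)
  if (length(missing_de)) {
    abort(sprintf(
      "DE table lacks %d template gene(s) (e.g. %s).",
      length(missing_de), missing_de[1]
    ))
  }
  lfc <- setNames(tumor_vs_cl_de$lfc, tumor_vs_cl_de$gene)
  sample_medians <- apply(cell_x, 2, median)
  top_half_counts <- rowSums(sweep(cell_x, 2, sample_medians, `>=`))

  prov <- templates$provenance
  new_templates <- templates$templates
  for (s in names(new_templates)) {
    genes <- new_templates[[s]]
    de_drop <- abs(lfc[genes]) > cl_de_cutoff
    present <- genes %in% rownames(cell_x)
    expr_drop <- !present | top_half_counts[genes] < min_cell_lines
    expr_drop[is.na(expr_drop)] <- TRUE
    status <- rep("kept", length(genes))
    status[expr_drop] <- "dropped_low_expression"
    status[de_drop] <- "dropped_tumor_cl_de" # DE rule takes precedence
    keep <- status == "kept"
    if (!any(keep)) {
      abort(sprintf("template for subtype %s emptied by filtering.", s))
    }
    rows <- which(prov$gene %in% genes & prov$subtype == s &
      prov$status == "kept")
    prov$status[rows] <- status[match(prov$gene[rows], genes)]
    new_templates[[s]] <- genes[keep]
  }
  structure(
    list(
      templates = new_templates, provenance = prov,
      params = c(templates$params, list(
        cl_de_cutoff = cl_de_cutoff, min_cell_lines = min_cell_lines
      ))
    ),
    class = "subtype_templates"
  )
}

#' Nearest-template subtype classification with resampling significance
#'
#' Expression is gene-standardized (z-scored) across the classified cohort;
#' each subtype's template is the binary vector that is 1 on its marker
#' genes and 0 elsewhere over the union of template genes; a sample is
#' predicted as the subtype whose template is nearest in cosine distance
#' (ties broken by subtype name order). Significance comes from
#' resampling: random marker sets of the same sizes are drawn from all
#' measured genes, and the nominal p is the smoothed fraction of resamples
#' whose best random-template distance is at most the observed one. BH-FDR
#' is taken across samples; a sample is assigned when FDR is at or below
#' `fdr_cutoff`.
#'
#' @param x Log-scale genes x samples matrix (the cohort to classify).
#' @param templates A `subtype_templates` object or named list of marker
#'   gene vectors.
#' @param n_resample Resampling iterations (default 1000).
#' @param seed Seed for the resampling draws.
#' @param fdr_cutoff Assignment FDR cutoff (default 0.05).
#' @param distance `"cosine"` (default) or `"correlation"`.
#' @param min_template_genes Minimum template genes that must be present in
#'   `x` for every subtype (default 5).
#' @return Tibble of class `ntp_calls`: `sample_id`, `subtype`, `distance`,
#'   `p_value`, `fdr`, `assigned`.
#' @export
ntp_classify <- function(x, templates, n_resample = 1000, seed = 1L,
                         fdr_cutoff = 0.05,
                         distance = c("cosine", "correlation"),
                         min_template_genes = 5) {
  distance <- match.arg(distance)
  check_expression_matrix(x, "x")
  if (inherits(templates, "subtype_templates")) {
    templates <- templates$templates
  }
  if (ncol(x) < 2) {
    abort("cohort of 1 sample cannot be z-scored; classify a larger cohort or standardize against a reference.")
  }
  templates <- lapply(templates, function(g) intersect(g, rownames(x)))
  short <- names(templates)[lengths(templates) < min_template_genes]
  if (length(short)) {
    abort(sprintf(
      "fewer than %d template genes present for subtype(s): %s",
      min_template_genes, paste(short, collapse = ", ")
    ))
  }
  subtypes <- sort(names(templates))
  templates <- templates[subtypes]
  sizes <- lengths(templates)

  zfull <- standardize_rows(x)
  union_genes <- sort(unique(unlist(templates)))
  zu <- zfull[union_genes, , drop = FALSE]
  tmat <- sapply(templates, function(g) as.numeric(union_genes %in% g))
  d_obs <- template_distances(zu, tmat, distance)
  best <- apply(d_obs, 2, which.min) # first index wins ties: name order
  d_best <- d_obs[cbind(best, seq_len(ncol(zu)))]

  n_genes <- nrow(x)
  total <- sum(sizes)
  hits <- withr::with_seed(seed, {
    acc <- numeric(ncol(x))
    for (r in seq_len(n_resample)) {
      draw <- sample.int(n_genes, total)
      rnd_union <- rownames(x)[draw]
      zr <- zfull[draw, , drop = FALSE]
      off <- 0L
      rmat <- matrix(0, total, length(sizes))
      for (k in seq_along(sizes)) {
        rmat[off + seq_len(sizes[k]), k] <- 1
        off <- off + sizes[k]
      }
      d_r <- template_distances(zr, rmat, distance)
      acc <- acc + (apply(d_r, 2, min) <= d_best)
    }
    acc
  })
  p <- (hits + 1) / (n_resample + 1)
  fdr <- p.adjust(p, method = "BH")
  structure(
    tibble(
      sample_id = colnames(x),
      subtype = subtypes[best],
      distance = unname(d_best),
      p_value = unname(p),
      fdr = unname(fdr),
      assigned = unname(fdr <= fdr_cutoff)
    ),
    class = c("ntp_calls", class(tibble())),
    params = list(
      n_resample = n_resample, seed = seed, fdr_cutoff = fdr_cutoff,
      distance = distance, template_sizes = sizes
    )
  )
}

standardize_rows <- function(x) {
  mu <- rowMeans(x)
  sds <- sqrt(rowMeans((x - mu)^2))
  sds[sds == 0] <- 1 # flat genes carry no information; z = 0
  (x - mu) / sds
}

# columns of z = samples; columns of tmat = subtypes. Cosine distance
# d = 1 - cos; correlation distance d = 1 - cor.
template_distances <- function(z, tmat, distance) {
  if (distance == "correlation") {
    z <- sweep(z, 2, colMeans(z))
    tmat <- sweep(tmat, 2, colMeans(tmat))
  }
  num <- crossprod(tmat, z) # subtypes x samples
  zn <- sqrt(colSums(z^2))
  tn <- sqrt(colSums(tmat^2))
  zn[zn == 0] <- .Machine$double.eps
  1 - num / outer(tn, zn)
}

#' Test-set accuracy and classification gate
#'
#' Accuracy over all test samples: a sample counts as correct only when it
#' is assigned and its predicted subtype matches the true label (the
#' stricter convention — unassigned samples are errors). The gate passes
#' when accuracy reaches `gate` (default 0.80), the precondition for
#' classifying cell lines.
#'
#' @param calls An [ntp_classify()] table.
#' @param true_labels Named character vector (or tibble `sample_id`,
#'   `subtype`) of true subtypes covering every call.
#' @param gate Accuracy threshold (default 0.80).
#' @return Tibble (`accuracy`, `n`, `n_correct`, `n_assigned`,
#'   `gate_passed`).
#' @export
evaluate_accuracy <- function(calls, true_labels, gate = 0.80) {
  if (is.data.frame(true_labels)) {
    true_labels <- setNames(true_labels$subtype, true_labels$sample_id)
  }
  miss <- setdiff(calls$sample_id, names(true_labels))
  if (length(miss)) {
    abort(sprintf("true labels missing for: %s", paste(miss, collapse = ", ")))
  }
  truth <- true_labels[calls$sample_id]
  correct <- calls$assigned & calls$subtype == truth
  acc <- mean(correct)
  tibble(
    accuracy = acc, n = nrow(calls), n_correct = sum(correct),
    n_assigned = sum(calls$assigned), gate_passed = acc >= gate
  )
}

#' Compare subtype proportions between tumors and cell lines
#'
#' Pearson chi-squared test (no continuity correction) on the
#' subtype x cohort contingency table; unassigned cell lines are excluded.
#'
#' @param tumor_labels Character vector of tumor subtype labels.
#' @param cell_calls An [ntp_classify()] table for the cell lines.
#' @return Tibble (`statistic`, `df`, `p_value`) with the contingency
#'   table attached as attribute `"table"`.
#' @export
subtype_proportion_test <- function(tumor_labels, cell_calls) {
  assigned <- cell_calls[cell_calls$assigned, , drop = FALSE]
  if (!nrow(assigned)) abort("no assigned cell-line calls.")
  subtypes <- sort(unique(c(tumor_labels, assigned$subtype)))
  tab <- rbind(
    tumor = table(factor(tumor_labels, levels = subtypes)),
    cell_line = table(factor(assigned$subtype, levels = subtypes))
  )
  if (length(subtypes) < 2) abort("need >= 2 subtypes with nonzero totals.")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("degenerate contingency table (zero row or column).")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn("expected count < 5 in at least one cell; chi-squared approximation is weak.")
  }
  structure(
    tibble(
      statistic = unname(ct$statistic), df = unname(ct$parameter),
      p_value = ct$p.value
    ),
    table = tab
  )
}

#' Per-subtype cell-line fidelity summaries
#'
#' Restricts the correlation matrix to each subtype's tumor columns and
#' summarizes cell lines within it, yielding subtype-specific rankings.
#'
#' @param C A [spearman_matrix()] result.
#' @param tumor_labels Named character vector (or tibble `sample_id`,
#'   `subtype`) of subtype labels for the tumor columns.
#' @return Tibble with a `subtype` column stacked over per-subtype
#'   summaries; subtypes without tumors are skipped with a warning.
#' @export
subtype_specific_ranks <- function(C, tumor_labels) {
  if (is.data.frame(tumor_labels)) {
    tumor_labels <- setNames(tumor_labels$subtype, tumor_labels$sample_id)
  }
  labs <- tumor_labels[colnames(C)]
  out <- list()
  for (s in sort(unique(stats::na.omit(labs)))) {
    cols <- which(!is.na(labs) & labs == s)
    if (!length(cols)) {
      warn(sprintf("subtype %s has no tumors; skipped.", s))
      next
    }
    sub <- summarize_cell_lines(C[, cols, drop = FALSE])
    sub$subtype <- s
    out[[s]] <- sub
  }
  dplyr::bind_rows(out)
}
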