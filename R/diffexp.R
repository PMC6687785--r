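#' Build the tumor-vs-cell-line design matrix
#'
#' Intercept, tumor indicator (1 = tumor, so positive log fold-changes are
#' up in tumors) and a purity covariate. Tumor samples use their purity
#' estimate; every cell line is fixed at purity 1, reflecting that cell
#' lines are pure cancer-cell populations.
#'
#' @param samples Metadata tibble with `sample_id` and `cohort`
#'   (tumor | cell_line) and, if `purity = TRUE`, a `purity` column with a
#'   value for every tumor.
#' @param purity Include the purity covariate (default `TRUE`).
#' @return Numeric samples x covariates matrix with columns
#'   `intercept`, `group`, and optionally `purity`.
#' @export
build_design <- function(samples, purity = TRUE) {
  need <- c("sample_id", "cohort")
  if (!all(need %in% colnames(samples))) {
    abort("`samples` needs columns sample_id and cohort.")
  }
  grp <- as.numeric(samples$cohort == "tumor")
  design <- cbind(intercept = 1, group = grp)
  if (purity) {
    if (!"purity" %in% colnames(samples)) {
      abort("`samples` lacks a purity column.")
    }
    p <- ifelse(samples$cohort == "cell_line", 1, samples$purity)
    if (anyNA(p)) {
      abort("tumor sample(s) without purity; supply estimates or purity = FALSE.")
    }
    design <- cbind(design, purity = p)
  }
  rownames(design) <- samples$sample_id
  design
}

#' Count precision weights from the mean-variance trend
#'
#' The voom-style procedure: log-counts-per-million are computed as
#' `log2((count + 0.5) / (libsize + 1) * 1e6)` (optionally quantile
#' normalized), a gene-wise linear model is fitted, and the square-root
#' residual standard deviations are regressed on average log-count by
#' locally weighted regression. Each observation's weight is the inverse
#' fourth power of the trend value at its fitted log-count — i.e. the
#' inverse of its predicted variance. The trend is floored at a small
#' positive value so degenerate (zero-residual) fits cannot yield infinite
#' weights.
#'
#' @param counts Non-negative genes x samples count matrix.
#' @param design Samples x covariates design matrix (see [build_design()]).
#' @param span Span of the lowess trend fit (default 0.5).
#' @param normalize Apply [quantile_normalize()] to the logCPM before
#'   fitting (default `TRUE`, matching quantile-normalized precision
#'   weighting).
#' @param trend_floor Lower bound on the sqrt-SD trend (default 0.05).
#' @return List of class `voom_data`: `logcpm`, `weights`, `design`,
#'   `lib_size`.
#' @export
voom_weights <- function(counts, design, span = 0.5, normalize = TRUE,
                         trend_floor = 0.05) {
  check_expression_matrix(counts, "counts", require_counts = TRUE)
  design <- as.matrix(design)
  if (nrow(design) != ncol(counts)) {
    abort("`design` must have one row per sample.")
  }
  if (ncol(counts) < ncol(design) + 1) {
    abort("need more samples than design columns.")
  }
  lib <- colSums(counts)
  if (any(lib <= 0)) abort("library sizes must be > 0.")
  y <- t(log2((t(counts) + 0.5) / (lib + 1) * 1e6))
  if (normalize && ncol(y) >= 2) {
    dn <- dimnames(y)
    y <- quantile_normalize(y)
    dimnames(y) <- dn
  }
  fit <- lm.fit(design, t(y))
  p <- fit$rank
  df_resid <- ncol(y) - p
  if (df_resid < 1) abort("no residual degrees of freedom.")
  sigma <- sqrt(colSums(as.matrix(fit$residuals)^2) / df_resid)
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  trend <- lowess(sx, sy, f = span)
  trend_fun <- stats::approxfun(trend$x, trend$y, rule = 2, ties = mean)
  fitted_logcpm <- t(design %*% fit$coefficients)
  fitted_logcount <- fitted_logcpm +
    matrix(log2(lib + 1), nrow(y), ncol(y), byrow = TRUE) - log2(1e6)
  w <- 1 / pmax(trend_fun(fitted_logcount), trend_floor)^4
  w <- matrix(w, nrow(y), ncol(y), dimnames = dimnames(y))
  structure(
    list(logcpm = y, weights = w, design = design, lib_size = lib),
    class = "voom_data"
  )
}

#' Gene-wise weighted least squares
#'
#' Fits each gene's linear model under observation weights, returning what
#' the moderated-t step needs: coefficients, unscaled coefficient standard
#' deviations, residual variances and degrees of freedom.
#'
#' @param y Genes x samples response matrix (e.g. logCPM).
#' @param weights Matrix of positive observation weights, same shape as `y`
#'   (or `NULL` for ordinary least squares).
#' @param design Samples x covariates design matrix; must be full rank.
#' @return List of class `wls_fit` with `coefficients` (genes x
#'   covariates), `stdev_unscaled`, `sigma2`, `df_residual`, `design`.
#' @export
fit_weighted_lm <- function(y, weights = NULL, design) {
  if (!is.matrix(y)) abort("`y` must be a matrix.")
  design <- as.matrix(design)
  if (nrow(design) != ncol(y)) abort("`design` must have one row per sample.")
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
    abort(sprintf(
      "design is rank deficient; collinear column(s): %s",
      paste(dropped, collapse = ", ")
    ))
  }
  if (is.null(weights)) weights <- matrix(1, nrow(y), ncol(y))
  if (!all(dim(weights) == dim(y))) abort("`weights` must match `y` in shape.")
  if (any(weights <= 0)) abort("weights must be positive.")
  ng <- nrow(y)
  p <- ncol(design)
  coef <- matrix(NA_real_, ng, p, dimnames = list(rownames(y), colnames(design)))
  stdev <- coef
  sigma2 <- numeric(ng)
  for (g in seq_len(ng)) {
    w <- weights[g, ]
    sw <- sqrt(w)
    Xw <- design * sw
    yw <- y[g, ] * sw
    f <- lm.fit(Xw, yw)
    xtx_inv <- solve(crossprod(Xw))
    coef[g, ] <- f$coefficients
    stdev[g, ] <- sqrt(diag(xtx_inv))
    sigma2[g] <- sum(f$residuals^2) / (ncol(y) - p)
  }
  structure(
    list(
      coefficients = coef, stdev_unscaled = stdev, sigma2 = sigma2,
      df_residual = ncol(y) - p, design = design
    ),
    class = "wls_fit"
  )
}

# limma-style Newton solve of trigamma(x) = y.
trigamma_inverse <- function(y) {
  out <- y
  omit <- !is.finite(y) | y <= 0
  out[y > 1e7] <- 1 / sqrt(y[y > 1e7])
  out[y < 1e-6] <- 1 / y[y < 1e-6]
  work <- !omit & y <= 1e7 & y >= 1e-6
  if (any(work)) {
    x <- 0.5 + 1 / y[work]
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / y[work]) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-8) break
    }
    out[work] <- x
  }
  out[omit & is.infinite(y)] <- 0
  out[omit & y <= 0] <- Inf
  out
}

#' Empirical-Bayes moderated t statistics
#'
#' Shrinks the gene-wise residual variances toward a common prior by the
#' standard empirical-Bayes scheme: the posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)` and the moderated t has `d0 + d`
#' degrees of freedom. The prior degrees of freedom `d0` and location
#' `s0^2` are estimated by matching the first two moments of `log(s^2)` to
#' the scaled-F prior predictive (closed-form moment equations via the
#' inverse trigamma). When the variances carry no excess spread, `d0` is
#' infinite and the pooled (prior) variance is used for every gene.
#'
#' @param fit A [fit_weighted_lm()] result.
#' @param coef Name of the coefficient tested (default `"group"`).
#' @param d0,s02 Optional prior values to inject instead of estimating
#'   (used for validation against closed forms).
#' @return Tibble of class `de_table`: `gene`, `lfc`, `t`, `p_value`,
#'   `fdr`, with attributes `d0`, `s02`, `df_residual`.
#' @export
ebayes_moderate <- function(fit, coef = "group", d0 = NULL, s02 = NULL) {
  stopifnot(inherits(fit, "wls_fit"))
  if (!coef %in% colnames(fit$coefficients)) {
    abort(sprintf("coefficient '%s' not in the design.", coef))
  }
  s2 <- fit$sigma2
  d <- fit$df_residual
  if (is.null(d0) || is.null(s02)) {
    if (length(s2) < 10) abort("need >= 10 genes to estimate the variance prior.")
    pr <- estimate_variance_prior(s2, d)
    d0 <- pr$d0
    s02 <- pr$s02
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  lfc <- fit$coefficients[, coef]
  tstat <- lfc / (fit$stdev_unscaled[, coef] * sqrt(s2_post))
  df_total <- min(d0 + d, 1e9)
  p <- 2 * pt(-abs(tstat), df_total)
  out <- tibble(
    gene = rownames(fit$coefficients) %||% as.character(seq_along(lfc)),
    lfc = unname(lfc), t = unname(tstat), p_value = unname(p),
    fdr = p.adjust(unname(p), method = "BH")
  )
  structure(out,
    class = c("de_table", class(out)),
    d0 = d0, s02 = s02, df_residual = d
  )
}

# Moment estimation of the variance prior (d0, s0^2) from log s^2.
estimate_variance_prior <- function(s2, d) {
  z <- log(pmax(s2, 1e-300))
  ok <- is.finite(z) & s2 > 0
  if (sum(ok) < 2) abort("too few positive residual variances.")
  e <- z[ok] - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess spread beyond chi-squared sampling noise: the prior scale
    # is not separately identified, so use the pooled variance
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

#' Apply differential-expression call cutoffs
#'
#' Flags genes with BH-FDR below `fdr_cutoff` and |LFC| above `lfc_cutoff`,
#' and labels the direction of change.
#'
#' @param table A `de_table` from [ebayes_moderate()].
#' @param lfc_cutoff Absolute log2 fold-change cutoff (default 2).
#' @param fdr_cutoff FDR cutoff (default 0.01).
#' @param direction_labels Length-2 character: labels for positive and
#'   negative LFC (defaults `up_in_tumor` / `up_in_cell_line`).
#' @return The table with `de` (logical) and `direction` columns.
#' @export
call_de <- function(table, lfc_cutoff = 2, fdr_cutoff = 0.01,
                    direction_labels = c("up_in_tumor", "up_in_cell_line")) {
  if (!all(c("lfc", "fdr") %in% colnames(table))) {
    abort("`table` must have lfc and fdr columns.")
  }
  table$de <- table$fdr < fdr_cutoff & abs(table$lfc) > lfc_cutoff
  table$direction <- ifelse(table$lfc > 0, direction_labels[1],
    direction_labels[2]
  )
  table
}

#' Genes consistently differential across tumor types
#'
#' @param tables Named list of called `de_table`s (one per tumor type).
#' @param min_types Minimum number of types a gene must be DE in.
#' @param direction Direction label to require (default `"up_in_tumor"`).
#' @return Character vector of gene IDs.
#' @export
consistent_genes <- function(tables, min_types, direction = "up_in_tumor") {
  if (length(tables) < min_types) {
    abort("`min_types` exceeds the number of tables.")
  }
  hits <- lapply(tables, function(tb) {
    tb$gene[tb$de & tb$direction == direction]
  })
  counts <- table(unlist(hits))
  sort(names(counts)[counts >= min_types])
}

#' Tumor-vs-cell-line differential expression, purity aware
#'
#' Convenience wrapper over the full count pipeline: precision weights from
#' the mean-variance trend on (quantile-normalized) logCPM, gene-wise
#' weighted least squares with tumor purity as a covariate (cell lines
#' fixed at purity 1), empirical-Bayes moderated t and BH-FDR, then call
#' cutoffs.
#'
#' @param counts Genes x samples count matrix.
#' @param samples Metadata tibble (`sample_id`, `cohort`, `purity`).
#' @param purity_covariate Include the purity covariate (default `TRUE`).
#' @param lfc_cutoff,fdr_cutoff Call cutoffs (defaults 2 and 0.01).
#' @param normalize Quantile-normalize the logCPM (default `TRUE`).
#' @return A called `de_table` (positive LFC = up in tumors).
#' @export
differential_expression <- function(counts, samples, purity_covariate = TRUE,
                                    lfc_cutoff = 2, fdr_cutoff = 0.01,
                                    normalize = TRUE) {
  if (!all(colnames(counts) == samples$sample_id)) {
    samples <- samples[match(colnames(counts), samples$sample_id), ]
  }
  design <- build_design(samples, purity = purity_covariate)
  vw <- voom_weights(counts, design, normalize = normalize)
  fit <- fit_weighted_lm(vw$logcpm, vw$weights, design)
  tab <- ebayes_moderate(fit, coef = "group")
  call_de(tab, lfc_cutoff = lfc_cutoff, fdr_cutoff = fdr_cutoff)
}
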