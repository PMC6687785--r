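#' Upper-quartile normalization
#'
#' Scales each sample so the 75th percentile of its nonzero counts equals
#' the geometric mean of those percentiles across samples. Percentiles use
#' linear interpolation between order statistics (quantile type 7) on the
#' nonzero counts only, the standard convention for sparse count data.
#'
#' @param counts Non-negative genes x samples matrix.
#' @return Scaled matrix; the per-sample scaling divisors are attached as
#'   attribute `"uq_factors"` (a factor of 1 leaves a sample unchanged).
#' @export
upper_quartile_normalize <- function(counts) {
  check_expression_matrix(counts, "counts", require_counts = TRUE)
  uq <- apply(counts, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) return(NA_real_)
    quantile(nz, 0.75, type = 7, names = FALSE)
  })
  if (anyNA(uq)) {
    abort(sprintf(
      "all-zero sample(s): %s", paste(colnames(counts)[is.na(uq)], collapse = ", ")
    ))
  }
  ref <- exp(mean(log(uq)))
  factors <- uq / ref
  out <- sweep(counts, 2, factors, `/`)
  attr(out, "uq_factors") <- setNames(factors, colnames(counts))
  out <- add_provenance(out, "uq_normalized")
  out
}

#' log2 transform with pseudocount
#'
#' @param x Non-negative matrix.
#' @param pseudocount Positive offset added before taking log2 (default 1).
#' @return `log2(x + pseudocount)` with provenance tag `log_transformed`.
#' @export
log_transform <- function(x, pseudocount = 1) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  if (any(x < 0)) abort("`x` must be non-negative.")
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort("`pseudocount` must be > 0.")
  }
  prov <- attr(x, "provenance")
  out <- log2(x + pseudocount)
  attr(out, "provenance") <- prov
  add_provenance(out, "log_transformed")
}

#' Quantile normalization
#'
#' Forces every sample onto the common empirical distribution: each sample's
#' sorted values are replaced by the across-sample mean of sorted values.
#' Tied values receive the mean of the reference values their ranks span.
#'
#' @param x Matrix with >= 2 samples (columns).
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("`x` must be a numeric matrix.")
  if (ncol(x) < 2) abort("quantile normalization needs >= 2 samples.")
  if (any(!is.finite(x))) abort("`x` contains non-finite values.")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    o <- order(x[, j])
    # contiguous groups of equal input values share the mean reference value
    out[o, j] <- stats::ave(ref, match(x[o, j], unique(x[o, j])), FUN = mean)
  }
  prov <- attr(x, "provenance")
  attr(out, "provenance") <- prov
  add_provenance(out, "quantile_normalized")
}
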