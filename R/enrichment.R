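#' Build a ranked gene list from scores
#'
#' Orders genes by score, descending, with ties broken deterministically by
#' gene ID. The classic (unweighted) enrichment statistic depends only on
#' this order.
#'
#' @param scores Named numeric vector (e.g. log2 fold-changes) or a
#'   `de_table` (ranked by `lfc`).
#' @return Named numeric vector sorted for enrichment analysis.
#' @export
ranked_list <- function(scores) {
  if (is.data.frame(scores)) {
    if (!all(c("gene", "lfc") %in% colnames(scores))) {
      abort("a data-frame input needs gene and lfc columns.")
    }
    scores <- setNames(scores$lfc, scores$gene)
  }
  if (is.null(names(scores)) || anyDuplicated(names(scores))) {
    abort("`scores` must be uniquely named by gene.")
  }
  scores[order(-scores, names(scores))]
}

#' Classic (unweighted) enrichment score
#'
#' Walks the ranked list accumulating +1/|hits| at set members and
#' -1/(N - |hits|) elsewhere; the enrichment score is the maximum-magnitude
#' deviation of this running sum, which always returns to zero at the end
#' of the list.
#'
#' @param ranked A [ranked_list()] (or character vector already in order).
#' @param gene_set Character vector of member genes.
#' @return List: `es`, `running_sum` (length N), `leading_edge` (genes up
#'   to the extremum for positive ES, after it for negative),
#'   `hit_indices`.
#' @export
enrichment_score <- function(ranked, gene_set) {
  genes <- if (is.character(ranked)) ranked else names(ranked)
  n <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) abort("gene set has no overlap with the ranked list.")
  if (nh == n) abort("gene set covers the whole ranked list.")
  inc <- ifelse(hit, 1 / nh, -1 / (n - nh))
  rs <- cumsum(inc)
  # exact magnitude ties between the peak and the trough go positive
  # (tolerance guards float noise between equivalent computation orders)
  es <- if (max(rs) >= -min(rs) - 1e-12) max(rs) else min(rs)
  i_max <- which(rs == es)[1]
  leading <- if (es >= 0) {
    genes[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    genes[i_max:n][hit[i_max:n]]
  }
  list(
    es = es, running_sum = rs, leading_edge = leading,
    hit_indices = which(hit)
  )
}

# ES from sorted hit positions only: O(|S|) per evaluation. Candidates for
# the extremum are the running-sum values at each hit and just before it.
es_from_positions <- function(pos, n) {
  s <- length(pos)
  pos <- sort(pos)
  k <- seq_len(s)
  at_hit <- k / s - (pos - k) / (n - s)
  before_hit <- (k - 1) / s - (pos - k) / (n - s)
  cand <- c(at_hit, before_hit, 0)
  if (max(cand) >= -min(cand) - 1e-12) max(cand) else min(cand)
}

#' Preranked gene set enrichment with permutation normalization
#'
#' Classic-mode preranked enrichment: for each set, the null distribution
#' of the enrichment score comes from `n_perm` random gene sets of the same
#' (intersected) size; NES divides ES by the mean magnitude of same-sign
#' null scores; the nominal p is the same-sign null tail fraction; and the
#' FDR q is the ratio-of-tails statistic over the pooled normalized null.
#'
#' @param ranked A [ranked_list()].
#' @param sets Named list of gene sets.
#' @param n_perm Number of random-set permutations (default 1000; values
#'   below 100 warn).
#' @param seed Seed for the permutation draws.
#' @param min_size,max_size Overlap-size bounds outside which a set is
#'   skipped with a warning (defaults 15 and 500).
#' @return Tibble of class `gsea_results`: `set`, `size`, `es`, `nes`,
#'   `p_value`, `q_value`, `leading_edge_size`, `leading_edge`
#'   (semicolon-joined).
#' @export
preranked_gsea <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           min_size = 15, max_size = 500) {
  if (n_perm < 100) warn("n_perm < 100 gives unstable q-values.")
  genes <- names(ranked)
  n <- length(genes)
  sizes <- vapply(sets, function(s) length(intersect(s, genes)), integer(1))
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep)) {
    warn(sprintf(
      "%d set(s) outside the size bounds were skipped.", sum(!keep)
    ))
  }
  sets <- sets[keep]
  sizes <- sizes[keep]
  if (!length(sets)) abort("no gene set within the size bounds.")

  obs <- lapply(sets, function(s) enrichment_score(genes, s))
  es <- vapply(obs, `[[`, numeric(1), "es")

  null_by_size <- withr::with_seed(seed, {
    out <- list()
    for (sz in sort(unique(sizes))) {
      out[[as.character(sz)]] <- vapply(
        seq_len(n_perm),
        function(i) es_from_positions(sample.int(n, sz), n),
        numeric(1)
      )
    }
    out
  })

  nes <- numeric(length(es))
  pval <- numeric(length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nul <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- mean(nul[nul > 0])
    neg_mean <- mean(abs(nul[nul < 0]))
    nes[i] <- if (es[i] >= 0) es[i] / pos_mean else es[i] / neg_mean
    if (es[i] >= 0) {
      pval[i] <- sum(nul >= es[i]) / max(sum(nul >= 0), 1)
    } else {
      pval[i] <- sum(nul <= es[i]) / max(sum(nul < 0), 1)
    }
    nn <- nul
    nn[nul >= 0] <- nul[nul >= 0] / pos_mean
    nn[nul < 0] <- nul[nul < 0] / neg_mean
    null_nes[[i]] <- nn
  }
  pooled <- unlist(null_nes)
  q <- vapply(seq_along(nes), function(i) {
    if (nes[i] >= 0) {
      num <- mean(pooled >= nes[i])
      den <- mean(nes >= nes[i])
    } else {
      num <- mean(pooled <= nes[i])
      den <- mean(nes <= nes[i])
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  tibble(
    set = names(sets), size = unname(sizes), es = unname(es),
    nes = nes, p_value = pval, q_value = q,
    leading_edge_size = vapply(obs, function(o) length(o$leading_edge),
      integer(1)
    ),
    leading_edge = vapply(obs, function(o) {
      paste(o$leading_edge, collapse = ";")
    }, character(1))
  ) |>
    structure(class = c("gsea_results", class(tibble())))
}

#' Filter enrichment results to significant sets
#'
#' Keeps sets with FDR q below the cutoff and labels the enrichment
#' direction from the NES sign: under the fixed positive-is-up-in-tumor
#' ranking convention, positive NES means enrichment toward the tumor end
#' and negative NES toward the cell-line end.
#'
#' @param results A [preranked_gsea()] table.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param direction_labels Labels for positive / negative NES.
#' @return Filtered tibble with a `direction` column.
#' @export
significant_sets <- function(results, q_cutoff = 0.05,
                             direction_labels = c("tumor", "cell_line")) {
  out <- results[results$q_value < q_cutoff, , drop = FALSE]
  out$direction <- ifelse(out$nes >= 0, direction_labels[1],
    direction_labels[2]
  )
  out
}
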