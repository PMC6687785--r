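#' Improved fixed-composition cell-line panel
#'
#' For each tumor type, selects the requested number of cell lines with the
#' highest median fidelity correlation (ties broken by cell-line ID), the
#' sort-and-slice construction behind the improved reference panel.
#'
#' @param summaries Tibble of per-cell-line summaries with columns
#'   `cell_line`, `tumor_type`, `median_rho` (e.g. stacked
#'   [summarize_cell_lines()] outputs).
#' @param composition Named integer vector (or tibble `tumor_type`, `count`)
#'   giving the number of cell lines per tumor type.
#' @return Tibble of class `panel_selection`: `cell_line`, `tumor_type`,
#'   `median_rho`, `subtype` (NA if absent), `reason = "rank_overall"`.
#' @export
improved_fixed_panel <- function(summaries, composition) {
  comp <- as_composition(composition)
  need <- c("cell_line", "tumor_type", "median_rho")
  if (!all(need %in% colnames(summaries))) {
    abort("`summaries` needs cell_line, tumor_type and median_rho columns.")
  }
  out <- list()
  for (i in seq_len(nrow(comp))) {
    tt <- comp$tumor_type[i]
    k <- comp$count[i]
    pool <- summaries |>
      dplyr::filter(.data$tumor_type == tt) |>
      dplyr::arrange(dplyr::desc(.data$median_rho), .data$cell_line)
    if (nrow(pool) < k) {
      abort(sprintf(
        "tumor type %s has %d cell line(s); %d requested.", tt, nrow(pool), k
      ))
    }
    sel <- pool[seq_len(k), ]
    sel$reason <- "rank_overall"
    out[[tt]] <- sel
  }
  finalize_panel(dplyr::bind_rows(out), "improved_fixed")
}

#' Subtype-diverse representative panel
#'
#' The 5-per-type panel construction: for tumor types with assigned subtype
#' calls, the top cell line within each assigned subtype is taken first
#' (subtypes ordered by their tumor-cohort prevalence, most prevalent
#' first) until `k` slots are filled or subtypes are exhausted; remaining
#' slots are filled by overall median correlation among the unchosen
#' lines. Types without calls fall back to the top-`k` overall.
#'
#' @param summaries As in [improved_fixed_panel()].
#' @param calls Tibble (`cell_line`, `subtype`, `assigned`) of cell-line
#'   subtype calls (e.g. [ntp_classify()] output with `sample_id` renamed),
#'   or `NULL` for no subtype information.
#' @param k Cell lines per tumor type (default 5).
#' @param tumor_subtypes Optional tibble (`tumor_type`, `subtype`) with one
#'   row per tumor sample, used to order subtypes by cohort prevalence;
#'   when absent, prevalence among the assigned cell-line calls is used.
#' @return Tibble of class `panel_selection` with `reason` either
#'   `"rank_within_subtype"` or `"rank_overall"`.
#' @export
subtype_diverse_panel <- function(summaries, calls = NULL, k = 5,
                                  tumor_subtypes = NULL) {
  need <- c("cell_line", "tumor_type", "median_rho")
  if (!all(need %in% colnames(summaries))) {
    abort("`summaries` needs cell_line, tumor_type and median_rho columns.")
  }
  if (!is.null(calls)) {
    if ("sample_id" %in% colnames(calls) && !"cell_line" %in% colnames(calls)) {
      calls <- dplyr::rename(calls, cell_line = "sample_id")
    }
    if (!"assigned" %in% colnames(calls)) calls$assigned <- TRUE
    calls <- calls[calls$assigned, c("cell_line", "subtype")]
  }
  out <- list()
  for (tt in sort(unique(summaries$tumor_type))) {
    pool <- summaries |>
      dplyr::filter(.data$tumor_type == tt) |>
      dplyr::arrange(dplyr::desc(.data$median_rho), .data$cell_line)
    kk <- k
    if (nrow(pool) < k) {
      warn(sprintf(
        "tumor type %s has %d cell line(s) (< %d); taking all.",
        tt, nrow(pool), k
      ))
      kk <- nrow(pool)
    }
    pool_calls <- if (is.null(calls)) {
      pool[0, ]
    } else {
      dplyr::inner_join(pool, calls, by = "cell_line", suffix = c("", ".call"))
    }
    chosen <- pool[0, ]
    if (nrow(pool_calls)) {
      sub_col <- if ("subtype.call" %in% colnames(pool_calls)) {
        "subtype.call"
      } else {
        "subtype"
      }
      prevalence <- subtype_prevalence(tt, pool_calls[[sub_col]], tumor_subtypes)
      for (s in prevalence) {
        if (nrow(chosen) >= kk) break
        cand <- pool_calls[pool_calls[[sub_col]] == s &
          !pool_calls$cell_line %in% chosen$cell_line, , drop = FALSE]
        if (!nrow(cand)) next
        pick <- cand[1, intersect(colnames(pool), colnames(cand))]
        pick$reason <- "rank_within_subtype"
        pick$panel_subtype <- s
        chosen <- dplyr::bind_rows(chosen, pick)
      }
    }
    fill <- pool[!pool$cell_line %in% chosen$cell_line, , drop = FALSE]
    n_fill <- kk - nrow(chosen)
    if (n_fill > 0) {
      add <- fill[seq_len(n_fill), ]
      add$reason <- "rank_overall"
      chosen <- dplyr::bind_rows(chosen, add)
    }
    out[[tt]] <- chosen
  }
  finalize_panel(dplyr::bind_rows(out), "subtype_diverse")
}

subtype_prevalence <- function(tt, call_subtypes, tumor_subtypes) {
  if (!is.null(tumor_subtypes)) {
    sub <- tumor_subtypes[tumor_subtypes$tumor_type == tt, , drop = FALSE]
    if (nrow(sub)) {
      tab <- sort(table(sub$subtype), decreasing = TRUE)
      ordered <- names(tab)
      # subtypes present only in calls come last, alphabetically
      return(c(ordered, sort(setdiff(unique(call_subtypes), ordered))))
    }
  }
  names(sort(table(call_subtypes), decreasing = TRUE))
}

as_composition <- function(composition) {
  if (is.data.frame(composition)) {
    if (!all(c("tumor_type", "count") %in% colnames(composition))) {
      abort("`composition` tibble needs tumor_type and count columns.")
    }
    return(as_tibble(composition[, c("tumor_type", "count")]))
  }
  if (is.null(names(composition))) {
    abort("`composition` must be named by tumor type.")
  }
  tibble(tumor_type = names(composition), count = as.integer(composition))
}

finalize_panel <- function(panel, name) {
  if (!"subtype" %in% colnames(panel)) panel$subtype <- NA_character_
  if (!"panel_subtype" %in% colnames(panel)) {
    panel$panel_subtype <- NA_character_
  }
  if (anyDuplicated(panel$cell_line)) {
    abort("panel construction produced duplicate cell lines.")
  }
  cols <- c(
    "cell_line", "tumor_type", "median_rho", "subtype", "panel_subtype",
    "reason"
  )
  panel <- panel[, intersect(cols, colnames(panel))]
  structure(panel,
    class = c("panel_selection", class(tibble())), panel_name = name
  )
}

#' Compare two panels' fidelity distributions
#'
#' Two-sided Wilcoxon rank-sum test on the per-cell-line median
#' correlations of two panels.
#'
#' @param panel_a,panel_b `panel_selection` tibbles (or any tibble with a
#'   `median_rho` column).
#' @param alternative Passed to [stats::wilcox.test()] (default
#'   `"two.sided"`).
#' @return Tibble (`statistic`, `p_value`, `n_a`, `n_b`,
#'   `median_a`, `median_b`).
#' @export
compare_panels <- function(panel_a, panel_b, alternative = "two.sided") {
  if (!nrow(panel_a) || !nrow(panel_b)) abort("both panels must be non-empty.")
  a <- panel_a$median_rho
  b <- panel_b$median_rho
  if (identical(sort(panel_a$cell_line), sort(panel_b$cell_line))) {
    warn("panels are identical; comparison is trivial.")
  }
  wt <- suppressWarnings(wilcox.test(a, b, alternative = alternative))
  tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_a = length(a), n_b = length(b),
    median_a = median(a), median_b = median(b)
  )
}

#' Simulate per-type cell-line fidelity summaries
#'
#' Generates the summary-level inputs panel construction consumes — one
#' block of cell lines per tumor type with random median correlations, and
#' subtype calls for a subset of types — without simulating full cohorts.
#' Useful for exercising panel construction at the scale of a multi-type
#' compendium.
#'
#' @param n_types Number of tumor types (default 22).
#' @param lines_per_type Cell lines per type (default 10).
#' @param n_subtypes Subtypes per subtyped tumor type (default 3).
#' @param subtyped_fraction Fraction of types with subtype calls
#'   (default 0.5).
#' @param seed Seed.
#' @return List: `summaries` tibble, `calls` tibble (`cell_line`,
#'   `subtype`, `assigned`), `tumor_subtypes` tibble of per-tumor labels.
#' @export
simulate_panel_summaries <- function(n_types = 22, lines_per_type = 10,
                                     n_subtypes = 3, subtyped_fraction = 0.5,
                                     seed = 1L) {
  withr::with_seed(seed, {
    types <- sprintf("TT%02d", seq_len(n_types))
    summaries <- dplyr::bind_rows(lapply(types, function(tt) {
      tibble(
        cell_line = sprintf("%s_CL%02d", tt, seq_len(lines_per_type)),
        tumor_type = tt,
        median_rho = round(runif(lines_per_type, 0.3, 0.8), 4)
      )
    }))
    subtyped <- sample(types, round(subtyped_fraction * n_types))
    calls <- dplyr::bind_rows(lapply(subtyped, function(tt) {
      lines <- summaries$cell_line[summaries$tumor_type == tt]
      tibble(
        cell_line = lines,
        subtype = sample(sprintf("S%d", seq_len(n_subtypes)),
          length(lines),
          replace = TRUE
        ),
        assigned = runif(length(lines)) < 0.7
      )
    }))
    tumor_subtypes <- dplyr::bind_rows(lapply(subtyped, function(tt) {
      tibble(
        tumor_type = tt,
        subtype = sample(sprintf("S%d", seq_len(n_subtypes)), 60,
          replace = TRUE
        )
      )
    }))
    list(summaries = summaries, calls = calls, tumor_subtypes = tumor_subtypes)
  })
}
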