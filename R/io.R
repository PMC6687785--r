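#' Read a genes x samples expression matrix from TSV
#'
#' Expects genes as rows, samples as columns, a header row of sample IDs and
#' gene IDs in the first column (the conventional expression-matrix dialect).
#'
#' @param path Path to a TSV file.
#' @param counts If `TRUE`, additionally require non-negative values.
#' @return Numeric matrix with gene rownames and sample colnames, in file
#'   order.
#' @export
read_expression_tsv <- function(path, counts = FALSE) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tab) < 2) abort("expression TSV needs a gene column plus >=1 sample.")
  gene_ids <- tab[[1]]
  sample_ids <- colnames(tab)[-1]
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    abort(sprintf("duplicated gene IDs: %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    dup <- unique(sample_ids[duplicated(sample_ids)])
    abort(sprintf("duplicated sample IDs: %s", paste(dup, collapse = ", ")))
  }
  mat <- matrix(NA_real_, nrow(tab), length(sample_ids),
    dimnames = list(gene_ids, sample_ids)
  )
  for (j in seq_along(sample_ids)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1]]))
    bad <- which(is.na(v) & !is.na(tab[[j + 1]]))
    if (length(bad)) {
      abort(sprintf(
        "non-numeric value '%s' at row %d (gene %s), column %s",
        tab[[j + 1]][bad[1]], bad[1], gene_ids[bad[1]], sample_ids[j]
      ))
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in column %s", sample_ids[j]))
    }
    mat[, j] <- v
  }
  check_expression_matrix(mat, "matrix", require_counts = counts)
  mat
}

#' Write an expression matrix as TSV
#'
#' Full-precision (round-trippable) numeric formatting; first column `gene`.
#'
#' @param x Genes x samples numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path) {
  check_expression_matrix(x)
  tab <- as_tibble(x, rownames = "gene")
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' Columns: `sample_id`, `cohort` (tumor | cell_line), `tumor_type`,
#' `purity`, `batch`, `subtype`. Missing purity/subtype entries may be empty
#' or `NA`.
#'
#' @param path Path to a TSV file.
#' @return Tibble of per-sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    cohort = readr::col_character(),
    tumor_type = readr::col_character(),
    purity = readr::col_double(),
    batch = readr::col_character(),
    subtype = readr::col_character()
  ), progress = FALSE)
  need <- c("sample_id", "cohort", "tumor_type", "purity", "batch", "subtype")
  miss <- setdiff(need, colnames(tab))
  if (length(miss)) {
    abort(sprintf("metadata lacks columns: %s", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tab$sample_id)) abort("duplicated sample_id in metadata.")
  bad <- setdiff(unique(tab$cohort), c("tumor", "cell_line"))
  if (length(bad)) {
    abort(sprintf("unknown cohort values: %s", paste(bad, collapse = ", ")))
  }
  ok <- is.na(tab$purity) | (tab$purity >= 0 & tab$purity <= 1)
  if (!all(ok)) abort("purity values must lie in [0, 1] or be missing.")
  tab
}

#' Write sample metadata TSV
#'
#' @param samples Tibble as produced by [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(samples, path) {
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then tab-separated gene IDs.
#' Duplicate genes within a set are collapsed with a warning; sets that are
#' empty after collapsing are dropped with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; descriptions kept as the
#'   `"descriptions"` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need >= 3.", i, length(fields)))
    }
    nm <- fields[1]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("set %s: duplicate genes collapsed.", nm))
      genes <- unique(genes)
    }
    if (!length(genes)) {
      warn(sprintf("set %s is empty after collapsing; dropped.", nm))
      next
    }
    sets[[nm]] <- genes
    descs[nm] <- fields[2]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Read gene sets from a GMX file (transposed GMT)
#'
#' Column-oriented variant: first row set names, second row descriptions,
#' then one gene per row per column.
#'
#' @param path Path to a GMX file.
#' @return Named list of character vectors.
#' @export
read_gmx <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) abort("GMX needs a name row, a description row and genes.")
  rows <- lapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
  n <- length(rows[[1]])
  sets <- list()
  for (j in seq_len(n)) {
    genes <- vapply(rows[-(1:2)], function(r) {
      if (length(r) >= j) r[j] else ""
    }, character(1))
    genes <- unique(genes[nzchar(genes)])
    if (length(genes)) sets[[rows[[1]][j]]] <- genes
  }
  sets
}

#' Write gene sets as GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    abort("all gene sets must be named.")
  }
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[nm] %||% "na"
    if (is.na(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' Writes `counts.tsv`, `metadata.tsv` and `truth_gene_roles.tsv` for a
#' synthetic cohort, the on-disk form the readers above consume.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$counts, file.path(dir, "counts.tsv"))
  write_sample_metadata(cohort$samples, file.path(dir, "metadata.tsv"))
  readr::write_tsv(cohort$truth$gene_roles,
    file.path(dir, "truth_gene_roles.tsv"),
    progress = FALSE
  )
  invisible(dir)
}
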