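#' Configuration for the synthetic tumor / cell-line cohort generator
#'
#' Defines the generative model the rest of the pipeline assumes: bulk tumors
#' are purity-weighted mixtures (on the linear count-expectation scale) of a
#' subtype-specific cancer profile and a shared immune/stromal contaminating
#' profile; cell lines are pure cancer profiles with a proliferation-module
#' upshift; a fraction of tumor samples receive additive per-gene log-scale
#' platform (batch) shifts; counts are negative binomial with log-normal
#' library-size factors.
#'
#' @param n_genes Number of genes.
#' @param n_tumors Number of primary tumor samples.
#' @param n_cell_lines Number of cell-line samples.
#' @param n_subtypes Number of discrete molecular subtypes.
#' @param n_marker_genes Marker genes per subtype (mean-shifted in that
#'   subtype's cancer profile).
#' @param subtype_logfc log2 effect of a subtype on its marker genes.
#' @param n_immune_genes Genes elevated in the contaminating profile.
#' @param immune_logfc log2 elevation of immune genes in the contaminating
#'   (immune/stromal) profile.
#' @param purity_beta_a,purity_beta_b Shape parameters of the Beta
#'   distribution tumor purity is drawn from. `purity_beta_a = Inf` fixes
#'   purity at 1 (no contamination).
#' @param n_proliferation_genes Genes upshifted in cell lines.
#' @param proliferation_logfc log2 cell-line upshift on proliferation genes.
#' @param batch_fraction Fraction of tumor samples assigned to the second
#'   sequencing platform.
#' @param batch_sd SD of the additive per-gene log2-scale platform shift.
#' @param nb_dispersion Global negative-binomial dispersion (1/size).
#' @param libsize_logsd SD of the log library-size factors (log-normal,
#'   mean 0 on the log scale).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `synthetic_config`.
#' @seealso [generate_cohort()]
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_tumors = 100,
                             n_cell_lines = 30,
                             n_subtypes = 3,
                             n_marker_genes = 30,
                             subtype_logfc = 2,
                             n_immune_genes = 150,
                             immune_logfc = 3,
                             purity_beta_a = 5,
                             purity_beta_b = 2,
                             n_proliferation_genes = 50,
                             proliferation_logfc = 1,
                             batch_fraction = 0.3,
                             batch_sd = 0.3,
                             nb_dispersion = 0.1,
                             libsize_logsd = 0.3,
                             seed = 1L) {
  cfg <- list(
    n_genes = n_genes, n_tumors = n_tumors, n_cell_lines = n_cell_lines,
    n_subtypes = n_subtypes, n_marker_genes = n_marker_genes,
    subtype_logfc = subtype_logfc, n_immune_genes = n_immune_genes,
    immune_logfc = immune_logfc, purity_beta_a = purity_beta_a,
    purity_beta_b = purity_beta_b,
    n_proliferation_genes = n_proliferation_genes,
    proliferation_logfc = proliferation_logfc,
    batch_fraction = batch_fraction, batch_sd = batch_sd,
    nb_dispersion = nb_dispersion, libsize_logsd = libsize_logsd,
    seed = as.integer(seed)
  )
  counts <- c(
    "n_genes", "n_tumors", "n_cell_lines", "n_subtypes", "n_marker_genes",
    "n_immune_genes", "n_proliferation_genes"
  )
  for (nm in counts) {
    v <- cfg[[nm]]
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v)) {
      abort(sprintf("`%s` must be a positive integer.", nm))
    }
  }
  if (!(purity_beta_a > 0) || !(purity_beta_b > 0)) {
    abort("purity Beta shape parameters must be > 0.")
  }
  if (batch_fraction < 0 || batch_fraction > 1) {
    abort("`batch_fraction` must lie in [0, 1].")
  }
  if (nb_dispersion <= 0 || libsize_logsd < 0 || batch_sd < 0) {
    abort("`nb_dispersion` must be > 0; `libsize_logsd` and `batch_sd` >= 0.")
  }
  n_special <- n_subtypes * n_marker_genes + n_immune_genes +
    n_proliferation_genes
  if (n_special > n_genes) {
    abort(sprintf(
      "marker (%d) + immune (%d) + proliferation (%d) genes exceed n_genes (%d).",
      n_subtypes * n_marker_genes, n_immune_genes, n_proliferation_genes,
      n_genes
    ))
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic tumor + cell-line expression cohort
#'
#' Draws a full cohort under the generative model of [synthetic_config()]:
#' disjoint marker / immune / proliferation / background gene roles, tumor
#' purity from a Beta distribution, linear-scale purity mixtures of cancer
#' and contaminating profiles, platform batch shifts on the log-mean scale
#' for a fraction of tumors, and negative-binomial counts with per-sample
#' library-size factors. The returned truth object carries everything an
#' oracle needs to recompute the closed-form expectations.
#'
#' @param config A [synthetic_config()].
#' @param tumor_type Label written to the metadata `tumor_type` column.
#' @return A list of class `synthetic_cohort` with elements
#'   * `counts`: genes x samples integer-valued matrix,
#'   * `samples`: tibble (`sample_id`, `cohort`, `tumor_type`, `purity`,
#'     `batch`, `subtype`),
#'   * `truth`: list with `gene_roles` tibble (`gene`, `role`), per-sample
#'     `purity`, `subtype`, `batch`, `lib_factor`, the per-gene
#'     `baseline_log2` means, `batch_shift` (log2 per-gene shift applied to
#'     platform 2), `expected_mean` (the linear-scale mean matrix the counts
#'     were drawn from) and the `config`.
#' @export
#' @examples
#' coh <- generate_cohort(synthetic_config(n_genes = 200, n_tumors = 20,
#'                                         n_cell_lines = 6, seed = 7))
#' dim(coh$counts)
#' dplyr::count(coh$samples, cohort)
generate_cohort <- function(config = synthetic_config(),
                            tumor_type = "TYPE1") {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  withr::with_seed(cf$seed, {
    genes <- sprintf("g%04d", seq_len(cf$n_genes))
    tumors <- sprintf("T%03d", seq_len(cf$n_tumors))
    cells <- sprintf("CL%03d", seq_len(cf$n_cell_lines))

    # Disjoint gene roles, assigned from a random permutation.
    perm <- sample(cf$n_genes)
    idx <- 0L
    marker_idx <- lapply(seq_len(cf$n_subtypes), function(k) {
      out <- perm[idx + seq_len(cf$n_marker_genes)]
      idx <<- idx + cf$n_marker_genes
      out
    })
    immune_idx <- perm[idx + seq_len(cf$n_immune_genes)]
    idx <- idx + cf$n_immune_genes
    prolif_idx <- perm[idx + seq_len(cf$n_proliferation_genes)]

    role <- rep("background", cf$n_genes)
    for (k in seq_len(cf$n_subtypes)) {
      role[marker_idx[[k]]] <- sprintf("marker_S%d", k)
    }
    role[immune_idx] <- "immune"
    role[prolif_idx] <- "proliferation"

    subtype_names <- sprintf("S%d", seq_len(cf$n_subtypes))

    # Baseline log2 means; cancer profile per subtype; contaminating profile.
    baseline_log2 <- rnorm(cf$n_genes, mean = 4, sd = 1.5)
    base_lin <- 2^baseline_log2
    cancer <- sapply(seq_len(cf$n_subtypes), function(k) {
      shift <- rep(0, cf$n_genes)
      shift[marker_idx[[k]]] <- cf$subtype_logfc
      base_lin * 2^shift
    })
    colnames(cancer) <- subtype_names
    immune_profile <- base_lin
    immune_profile[immune_idx] <- immune_profile[immune_idx] * 2^cf$immune_logfc

    # Sample-level truth.
    tumor_subtype <- sample(rep_len(subtype_names, cf$n_tumors))
    cell_subtype <- sample(rep_len(subtype_names, cf$n_cell_lines))
    purity <- if (is.infinite(cf$purity_beta_a)) {
      rep(1, cf$n_tumors)
    } else {
      rbeta(cf$n_tumors, cf$purity_beta_a, cf$purity_beta_b)
    }
    n_batch2 <- round(cf$batch_fraction * cf$n_tumors)
    batch2 <- sample(cf$n_tumors, n_batch2)
    batch <- rep("platform1", cf$n_tumors)
    batch[batch2] <- "platform2"
    batch_shift <- rnorm(cf$n_genes, 0, cf$batch_sd)

    # Linear-scale expected means: tumors are purity mixtures, cell lines
    # pure cancer profiles with the proliferation upshift.
    mu_t <- sapply(seq_len(cf$n_tumors), function(s) {
      p <- purity[s]
      mu <- p * cancer[, tumor_subtype[s]] + (1 - p) * immune_profile
      if (batch[s] == "platform2") mu <- mu * 2^batch_shift
      mu
    })
    prolif_fac <- rep(1, cf$n_genes)
    prolif_fac[prolif_idx] <- 2^cf$proliferation_logfc
    mu_c <- sapply(seq_len(cf$n_cell_lines), function(s) {
      cancer[, cell_subtype[s]] * prolif_fac
    })
    mu <- cbind(mu_t, mu_c)
    lib_factor <- exp(rnorm(cf$n_tumors + cf$n_cell_lines, 0, cf$libsize_logsd))
    mu_scaled <- sweep(mu, 2, lib_factor, `*`)

    counts <- matrix(
      rnbinom(length(mu_scaled), mu = mu_scaled, size = 1 / cf$nb_dispersion),
      nrow = cf$n_genes
    )
    counts <- counts * 1.0 # store as double for downstream arithmetic
    sample_ids <- c(tumors, cells)
    dimnames(counts) <- list(genes, sample_ids)
    dimnames(mu) <- list(genes, sample_ids)

    samples <- tibble(
      sample_id = sample_ids,
      cohort = rep(c("tumor", "cell_line"), c(cf$n_tumors, cf$n_cell_lines)),
      tumor_type = tumor_type,
      purity = c(purity, rep(NA_real_, cf$n_cell_lines)),
      batch = c(batch, rep("cell_line", cf$n_cell_lines)),
      subtype = c(tumor_subtype, cell_subtype)
    )

    truth <- list(
      gene_roles = tibble(gene = genes, role = role),
      purity = setNames(purity, tumors),
      subtype = setNames(c(tumor_subtype, cell_subtype), sample_ids),
      batch = setNames(batch, tumors),
      lib_factor = setNames(lib_factor, sample_ids),
      baseline_log2 = setNames(baseline_log2, genes),
      batch_shift = setNames(batch_shift, genes),
      expected_mean = mu,
      config = cf
    )
    structure(list(counts = counts, samples = samples, truth = truth),
      class = "synthetic_cohort"
    )
  })
}

#' Build gene-set collections from a synthetic truth
#'
#' Emits the immune set, the proliferation set, one marker set per subtype,
#' and `n_random_sets` uniformly drawn background sets, as a GMT-serializable
#' named list (the synthetic stand-in for curated hallmark collections).
#'
#' @param truth The `truth` element of a [generate_cohort()] result.
#' @param n_random_sets Number of random sets to add.
#' @param set_size Size of each random set.
#' @param seed Seed for the random draws.
#' @return Named list of character vectors of gene IDs.
#' @export
generate_gene_sets <- function(truth, n_random_sets = 10, set_size = 50,
                               seed = 1L) {
  roles <- truth$gene_roles
  if (set_size >= nrow(roles)) abort("`set_size` must be < n_genes.")
  sets <- list(
    IMMUNE = roles$gene[roles$role == "immune"],
    PROLIFERATION = roles$gene[roles$role == "proliferation"]
  )
  marker_roles <- sort(unique(roles$role[startsWith(roles$role, "marker_")]))
  for (r in marker_roles) {
    sets[[paste0("MARKERS_", sub("^marker_", "", r))]] <-
      roles$gene[roles$role == r]
  }
  if (n_random_sets > 0) {
    rnd <- withr::with_seed(seed, {
      lapply(seq_len(n_random_sets), function(i) sample(roles$gene, set_size))
    })
    names(rnd) <- sprintf("RANDOM_%02d", seq_len(n_random_sets))
    sets <- c(sets, rnd)
  }
  sets
}
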