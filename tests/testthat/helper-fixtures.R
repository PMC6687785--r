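# Shared fixtures, generated in code. The default cohort is cached per test
# run so independent test files do not regenerate it.

small_config <- function(...) {
  args <- utils::modifyList(
    list(
      n_genes = 300, n_tumors = 40, n_cell_lines = 10, n_subtypes = 2,
      n_marker_genes = 15, n_immune_genes = 30, n_proliferation_genes = 15,
      seed = 42L
    ),
    list(...)
  )
  do.call(synthetic_config, args)
}

default_cohort_cache <- new.env(parent = emptyenv())

default_cohort <- function() {
  if (is.null(default_cohort_cache$coh)) {
    default_cohort_cache$coh <- generate_cohort(synthetic_config())
  }
  default_cohort_cache$coh
}

# A small matrix with reproducible values and proper dimnames.
toy_matrix <- function(n_genes = 6, n_samples = 4, seed = 1, offset = 0) {
  withr::with_seed(seed, {
    m <- matrix(
      round(runif(n_genes * n_samples, 1, 100)) + offset,
      n_genes, n_samples,
      dimnames = list(
        sprintf("g%02d", seq_len(n_genes)),
        sprintf("s%02d", seq_len(n_samples))
      )
    )
    m
  })
}

# log-scale gaussian matrix for normalization / regression tests
gauss_matrix <- function(n_genes = 50, n_samples = 12, seed = 3, mean = 6) {
  withr::with_seed(seed, {
    matrix(rnorm(n_genes * n_samples, mean, 1), n_genes, n_samples,
      dimnames = list(
        sprintf("g%03d", seq_len(n_genes)),
        sprintf("s%03d", seq_len(n_samples))
      )
    )
  })
}
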