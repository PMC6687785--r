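# Subtype cohort at the scale the classifier is meant for
subtype_cohort <- function(seed = 1, n_tumors = 150, subtype_logfc = 2,
                           n_cell_lines = 30) {
  generate_cohort(synthetic_config(
    n_tumors = n_tumors, n_cell_lines = n_cell_lines,
    subtype_logfc = subtype_logfc, seed = seed
  ))
}

test_that("stratified split allocates per subtype and reproduces", {
  ids <- sprintf("s%03d", 1:100)
  labels <- rep(c("A", "B"), each = 50)
  sp <- split_train_test(ids, labels, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(sum(labels[match(sp$train, ids)] == "A"), 40)
  expect_equal(sum(labels[match(sp$test, ids)] == "B"), 10)

  sp2 <- split_train_test(ids, labels, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_train_test(ids, labels, seed = 2)
  expect_false(identical(sp, sp3))

  # 5 subtypes x 10 samples: 8 train / 2 test each (stratified enumeration)
  ids5 <- sprintf("t%02d", 1:50)
  lab5 <- rep(sprintf("S%d", 1:5), each = 10)
  sp5 <- split_train_test(ids5, lab5, seed = 3)
  for (s in unique(lab5)) {
    expect_equal(sum(lab5[match(sp5$train, ids5)] == s), 8)
    expect_equal(sum(lab5[match(sp5$test, ids5)] == s), 2)
  }

  expect_error(
    split_train_test(c("a", "b", "c"), c("A", "A", "B")),
    "single sample"
  )
})

test_that("template derivation recovers planted markers and stays disjoint", {
  coh <- subtype_cohort(seed = 1)
  norm <- log_transform(upper_quartile_normalize(coh$counts))
  tumors <- coh$samples$sample_id[coh$samples$cohort == "tumor"]
  labels <- coh$truth$subtype[tumors]
  tpl <- build_templates(norm[, tumors], labels)
  roles <- coh$truth$gene_roles
  for (s in names(tpl$templates)) {
    planted <- roles$gene[roles$role == paste0("marker_", s)]
    recovered <- intersect(tpl$templates[[s]], planted)
    expect_gte(length(recovered), 0.9 * length(planted))
  }
  # disjoint across subtypes
  expect_equal(anyDuplicated(unlist(tpl$templates)), 0L)
})

test_that("identical subtypes produce no template genes", {
  x <- gauss_matrix(60, 20)
  labels <- rep(c("A", "B"), 10) # labels carry no signal
  expect_error(build_templates(x, labels), "no template genes")
})

test_that("multi-subtype qualifying genes go to the max-LFC subtype", {
  # plant a gene up in both subtypes vs the third, stronger in B
  withr::with_seed(2, {
    n <- 60
    x <- matrix(rnorm(50 * n, 5, 0.3), 50, n,
      dimnames = list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:n))
    )
    labels <- rep(c("A", "B", "C"), each = 20)
    x["g01", labels == "A"] <- x["g01", labels == "A"] + 1.5
    x["g01", labels == "B"] <- x["g01", labels == "B"] + 2.5
    # give every subtype its own clean markers so none ends empty
    x["g02", labels == "A"] <- x["g02", labels == "A"] + 3
    x["g03", labels == "B"] <- x["g03", labels == "B"] + 3
    x["g04", labels == "C"] <- x["g04", labels == "C"] + 3
  })
  tpl <- build_templates(x, labels)
  expect_true("g01" %in% tpl$templates$B)
  expect_false("g01" %in% tpl$templates$A)
})

test_that("cell-line relevance filter applies both removal rules", {
  tpl <- structure(
    list(
      templates = list(A = c("g1", "g2", "g3"), B = c("g4", "g5")),
      provenance = tibble::tibble(
        gene = c("g1", "g2", "g3", "g4", "g5"),
        subtype = c("A", "A", "A", "B", "B"),
        lfc = 2, fdr = 0.001, status = "kept"
      ),
      params = list()
    ),
    class = "subtype_templates"
  )
  de <- tibble::tibble(
    gene = c("g1", "g2", "g3", "g4", "g5"),
    lfc = c(3, 0.5, 0.1, -2.5, 0)
  )
  # cell matrix: 3 cell lines, 6 genes; sample median decides "top half"
  cell_x <- matrix(
    c(
      9, 9, 9, # g1 high everywhere
      9, 9, 9, # g2 high everywhere
      1, 1, 9, # g3 above median in only one line
      9, 9, 9, # g4
      9, 9, 1, # g5 above median in exactly two lines
      1, 1, 1, # filler low gene
      1, 1, 1, # filler low gene
      2, 2, 2 # filler low gene
    ), 8, 3,
    byrow = TRUE,
    dimnames = list(paste0("g", c(1:5, 6:8)), c("c1", "c2", "c3"))
  )
  out <- filter_templates_for_cell_lines(tpl, de, cell_x)
  expect_equal(out$templates$A, "g2") # g1 dropped by DE, g3 by expression
  expect_equal(out$templates$B, "g5") # g4 dropped by DE; g5 kept (exactly 2)
  prov <- out$provenance
  expect_equal(prov$status[prov$gene == "g1"], "dropped_tumor_cl_de")
  expect_equal(prov$status[prov$gene == "g3"], "dropped_low_expression")
  expect_equal(prov$status[prov$gene == "g4"], "dropped_tumor_cl_de")

  # emptying a template errors
  de_all <- de
  de_all$lfc <- 5
  expect_error(filter_templates_for_cell_lines(tpl, de_all, cell_x), "emptied")
})

test_that("immune template genes are filtered out for cell lines", {
  coh <- subtype_cohort(seed = 2)
  norm <- log_transform(upper_quartile_normalize(coh$counts))
  smp <- coh$samples
  tumors <- smp$sample_id[smp$cohort == "tumor"]
  cells <- smp$sample_id[smp$cohort == "cell_line"]
  labels <- coh$truth$subtype[tumors]
  tpl <- build_templates(norm[, tumors], labels)
  # plant an immune-role gene that is essentially absent in the pure cell
  # lines (lowest baseline): the top-half-expression rule must catch it
  roles <- coh$truth$gene_roles
  imm_all <- roles$gene[roles$role == "immune"]
  imm <- imm_all[which.min(coh$truth$baseline_log2[imm_all])]
  de_pre <- differential_expression(coh$counts, smp)
  med <- apply(norm[, cells], 2, median)
  expect_lt(sum(norm[imm, cells] >= med), 2)
  tpl$templates[[1]] <- c(tpl$templates[[1]], imm)
  tpl$provenance <- dplyr::bind_rows(
    tpl$provenance,
    tibble::tibble(
      gene = imm, subtype = names(tpl$templates)[1],
      lfc = 2, fdr = 1e-5, status = "kept"
    )
  )
  out <- filter_templates_for_cell_lines(tpl, de_pre, norm[, cells])
  # immune genes are absent from pure cell lines: caught by a filter rule
  expect_false(imm %in% out$templates[[1]])
})

test_that("nearest-template calls behave at the contracts' edges", {
  # perfect template match: z-profile 1 on A's markers, 0 elsewhere
  templates <- list(A = paste0("g", 1:5), B = paste0("g", 6:10))
  withr::with_seed(3, {
    n_genes <- 40
    x <- matrix(rnorm(n_genes * 20, 5, 1), n_genes, 20,
      dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:20))
    )
  })
  # engineer sample s1 so its z-scores over the union are exactly the A
  # template: force g1..g5 high by a fixed amount, g6..g10 at the mean
  zx <- x
  zx[1:5, 1] <- apply(x[1:5, ], 1, mean) + 3 * apply(x[1:5, ], 1, sd)
  calls <- ntp_classify(zx, templates, n_resample = 200, seed = 9)
  expect_equal(calls$subtype[1], "A")
  expect_lte(calls$distance[1], min(calls$distance[-1]) + 1)

  # nominal p bounds: never 0, never above 1
  expect_true(all(calls$p_value > 0 & calls$p_value <= 1))

  # distance ties break by subtype name order deterministically
  flat <- matrix(rnorm(40 * 3, 0, 1e-8), 40, 3,
    dimnames = list(paste0("g", 1:40), paste0("s", 1:3))
  )
  sym <- ntp_classify(flat, list(B = paste0("g", 1:5), A = paste0("g", 1:5)),
    n_resample = 50, seed = 1
  )
  expect_true(all(sym$subtype == "A")) # identical templates: name order wins

  expect_error(
    ntp_classify(x[, 1, drop = FALSE], templates, n_resample = 50, seed = 1),
    "z-scored"
  )
  expect_error(
    ntp_classify(x, list(A = c("g1", "zz1", "zz2", "zz3", "zz4")),
      n_resample = 50, seed = 1
    ),
    "template genes present"
  )
})

test_that("a perfect-match profile attains the smoothing floor p-value", {
  templates <- list(A = paste0("g", 1:6), B = paste0("g", 7:12))
  n_genes <- 500
  withr::with_seed(4, {
    x <- matrix(rnorm(n_genes * 30, 5, 1), n_genes, 30,
      dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:30))
    )
  })
  # sample 1: extreme elevation of A markers only
  x[1:6, 1] <- x[1:6, 1] + 8
  n_res <- 400
  calls <- ntp_classify(x, templates, n_resample = n_res, seed = 2)
  expect_equal(calls$subtype[1], "A")
  expect_equal(calls$p_value[1], 1 / (n_res + 1))
})

test_that("classification is invariant to gene order and affine rescaling", {
  coh <- subtype_cohort(seed = 3, n_tumors = 40, n_cell_lines = 10)
  norm <- log_transform(upper_quartile_normalize(coh$counts))
  cells <- coh$samples$sample_id[coh$samples$cohort == "cell_line"]
  roles <- coh$truth$gene_roles
  templates <- lapply(
    sort(unique(roles$role[startsWith(roles$role, "marker_")])),
    function(r) roles$gene[roles$role == r]
  )
  names(templates) <- sub("marker_", "", sort(unique(
    roles$role[startsWith(roles$role, "marker_")]
  )))
  x <- norm[, cells]
  c1 <- ntp_classify(x, templates, n_resample = 100, seed = 5)
  perm <- withr::with_seed(6, sample(nrow(x)))
  c2 <- ntp_classify(x[perm, ], templates, n_resample = 100, seed = 5)
  expect_equal(c1$subtype, c2$subtype)
  expect_equal(c1$distance, c2$distance, tolerance = 1e-10)
  c3 <- ntp_classify(3 * x + 7, templates, n_resample = 100, seed = 5)
  expect_equal(c1$distance, c3$distance, tolerance = 1e-10)
})

test_that("accuracy gate counts unassigned samples as errors", {
  calls <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    subtype = rep(c("A", "B"), 5),
    distance = 0.2, p_value = 0.001,
    fdr = c(rep(0.01, 8), 0.5, 0.5),
    assigned = c(rep(TRUE, 8), FALSE, FALSE)
  )
  truth <- setNames(rep(c("A", "B"), 5), calls$sample_id)
  acc <- evaluate_accuracy(calls, truth)
  expect_equal(acc$accuracy, 0.8)
  expect_true(acc$gate_passed) # boundary: >= 80%

  none <- calls
  none$assigned <- FALSE
  acc0 <- evaluate_accuracy(none, truth)
  expect_equal(acc0$accuracy, 0)
  expect_false(acc0$gate_passed)
})

test_that("subtype proportion test matches the closed-form chi-squared", {
  tumor_labels <- rep(c("basal", "classical"), c(30, 10))
  cell_calls <- tibble::tibble(
    sample_id = sprintf("c%02d", 1:40),
    subtype = rep(c("basal", "classical"), c(10, 30)),
    distance = 0.1, p_value = 0.001, fdr = 0.01, assigned = TRUE
  )
  res <- subtype_proportion_test(tumor_labels, cell_calls)
  # closed form for the 2x2 table (30,10 / 10,30)
  tab <- matrix(c(30, 10, 10, 30), 2, byrow = TRUE)
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  x2 <- sum((tab - expected)^2 / expected)
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, stats::pchisq(x2, 1, lower.tail = FALSE),
    tolerance = 1e-12
  )

  # identical proportions at large n: null
  cc2 <- cell_calls
  cc2$subtype <- rep(c("basal", "classical"), c(30, 10))
  expect_gt(subtype_proportion_test(tumor_labels, cc2)$p_value, 0.05)

  # empty calls error
  cc3 <- cell_calls
  cc3$assigned <- FALSE
  expect_error(subtype_proportion_test(tumor_labels, cc3), "no assigned")
})

test_that("subtype-specific rankings partition the pooled summary", {
  withr::with_seed(15, {
    C <- matrix(runif(4 * 30, 0.2, 0.9), 4, 30,
      dimnames = list(paste0("cl", 1:4), paste0("t", 1:30))
    )
  })
  labs <- setNames(rep(c("A", "B", "C"), each = 10), colnames(C))
  per <- subtype_specific_ranks(C, labs)
  expect_setequal(unique(per$subtype), c("A", "B", "C"))
  # single subtype reduces to the plain summary
  one <- subtype_specific_ranks(C[, 1:10], labs[1:10])
  plain <- summarize_cell_lines(C[, 1:10])
  expect_equal(one$median_rho, plain$median_rho)
  # shuffling labels changes per-subtype medians but not the pooled one
  labs_shuf <- setNames(withr::with_seed(16, sample(labs)), names(labs))
  per2 <- subtype_specific_ranks(C, labs_shuf)
  expect_equal(
    summarize_cell_lines(C)$median_rho,
    summarize_cell_lines(C)$median_rho
  )
  expect_false(identical(per$median_rho, per2$median_rho))
})

test_that("full subtype workflow passes the gate and recovers cell lines", {
  coh <- subtype_cohort(seed = 1)
  res <- classify_subtypes(coh$counts, coh$samples,
    config = pipeline_config(n_resample = 300, seed = 1)
  )
  expect_gte(res$accuracy$accuracy, 0.80)
  expect_true(res$accuracy$gate_passed)
  cl <- res$cell_line_calls
  expect_false(is.null(cl))
  truth <- coh$truth$subtype[cl$sample_id]
  agree <- mean(cl$subtype[cl$assigned] == truth[cl$assigned])
  expect_gte(agree, 0.9)
})
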