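# NB count fixture with planted tumor/cell-line effects
de_fixture <- function(n_genes = 400, n_planted = 40, n_per = 10, lfc = 4,
                       dispersion = 0.1, seed = 1) {
  withr::with_seed(seed, {
    base <- 2^rnorm(n_genes, 6, 1)
    fold <- rep(1, n_genes)
    planted <- seq_len(n_planted)
    fold[planted] <- 2^lfc
    mu <- cbind(
      matrix(base * fold, n_genes, n_per), # tumors: planted genes up
      matrix(base, n_genes, n_per)
    )
    counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / dispersion),
      n_genes,
      dimnames = list(
        sprintf("g%04d", seq_len(n_genes)),
        c(sprintf("T%02d", 1:n_per), sprintf("C%02d", 1:n_per))
      )
    )
    samples <- tibble::tibble(
      sample_id = colnames(counts),
      cohort = rep(c("tumor", "cell_line"), each = n_per),
      purity = c(rbeta(n_per, 5, 2), rep(NA, n_per))
    )
    list(counts = counts, samples = samples, planted = rownames(counts)[planted])
  })
}

test_that("design matrix fixes cell-line purity at 1", {
  fx <- de_fixture()
  d <- build_design(fx$samples)
  expect_equal(colnames(d), c("intercept", "group", "purity"))
  expect_true(all(d[fx$samples$cohort == "cell_line", "purity"] == 1))
  expect_true(all(d[fx$samples$cohort == "tumor", "group"] == 1))
  expect_equal(qr(d)$rank, 3)

  bad <- fx$samples
  bad$purity[1] <- NA
  expect_error(build_design(bad), "without purity")
})

test_that("logCPM follows the offset formula (plug-in oracle)", {
  counts <- matrix(c(0, 1e6 - 10, 10, 5e5, 4e5, 1e5), 3, 2,
    dimnames = list(c("gA", "gB", "gC"), c("s1", "s2"))
  )
  design <- cbind(intercept = c(1, 1))
  vw <- voom_weights(counts, design, normalize = FALSE)
  expect_equal(
    vw$logcpm["gA", "s1"],
    log2((0 + 0.5) / (1e6 + 1) * 1e6),
    tolerance = 1e-12
  )
  expect_equal(vw$logcpm["gA", "s1"], -1, tolerance = 1e-5)
})

test_that("degenerate residuals get floored weights, never infinite", {
  m <- toy_matrix(30, 1, seed = 2)
  counts <- cbind(s1 = m[, 1], s2 = m[, 1]) # identical samples
  rownames(counts) <- rownames(m)
  design <- cbind(intercept = c(1, 1))
  vw <- voom_weights(counts, design, normalize = FALSE)
  expect_true(all(is.finite(vw$weights)))
  expect_true(all(vw$weights <= 1 / 0.05^4 + 1e-9))
})

test_that("precision weights agree with the reference voom", {
  skip_if_not_installed("limma")
  fx <- de_fixture(n_genes = 300, seed = 4)
  design <- build_design(fx$samples)
  vw <- voom_weights(fx$counts, design, normalize = FALSE)
  ref <- limma::voom(fx$counts, design, span = 0.5)
  expect_equal(vw$logcpm, ref$E, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(vw$weights, ref$weights, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("Poisson-like data yields a nearly flat trend and similar weights", {
  withr::with_seed(6, {
    counts <- matrix(rpois(500 * 20, 200), 500, 20,
      dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:20))
    )
  })
  design <- cbind(intercept = rep(1, 20))
  vw <- voom_weights(counts, design, normalize = FALSE)
  w <- vw$weights
  # the bulk of the weights lie within 20% of each other (lowess tilt over
  # the narrow abundance range makes the extreme tails slightly wider)
  qs <- quantile(w, c(0.1, 0.9))
  expect_lt(qs[2] / qs[1], 1.2)
  expect_lt(max(w) / min(w), 1.6)
})

test_that("weighted least squares matches closed forms", {
  # exact fit: y = design beta exactly -> coefficients = beta, s2 = 0
  design <- cbind(intercept = 1, group = c(0, 0, 1, 1), purity = c(1, .5, 1, 1))
  beta <- c(2, -1, 0.5)
  y <- matrix(as.vector(design %*% beta), 1, 4,
    dimnames = list("g1", paste0("s", 1:4))
  )
  fit <- fit_weighted_lm(y, NULL, design)
  expect_equal(unname(fit$coefficients[1, ]), beta, tolerance = 1e-10)
  expect_equal(fit$sigma2[1], 0, tolerance = 1e-12)

  # hand-computable simple regression, 4 points
  x <- c(0, 1, 2, 3)
  yy <- c(1, 3, 4, 8)
  slope <- sum((x - mean(x)) * (yy - mean(yy))) / sum((x - mean(x))^2)
  intercept <- mean(yy) - slope * mean(x)
  d2 <- cbind(intercept = 1, group = x)
  f2 <- fit_weighted_lm(matrix(yy, 1, 4, dimnames = list("g", paste0("s", 1:4))),
    NULL, d2
  )
  expect_equal(unname(f2$coefficients[1, ]), c(intercept, slope),
    tolerance = 1e-12
  )

  # doubling weights changes nothing
  w1 <- matrix(c(1, 2, 1, 3), 1, 4)
  fa <- fit_weighted_lm(y, w1, design)
  fb <- fit_weighted_lm(y, 2 * w1, design)
  expect_equal(fa$coefficients, fb$coefficients, tolerance = 1e-12)
  expect_equal(fa$sigma2, fb$sigma2, tolerance = 1e-12)

  # rank deficiency is named
  d3 <- cbind(intercept = 1, group = c(1, 1, 1, 1))
  expect_error(fit_weighted_lm(y, NULL, d3), "group")
})

test_that("moderated t with injected prior equals the closed form", {
  withr::with_seed(9, {
    n <- 50
    design <- cbind(intercept = 1, group = rep(c(0, 1), each = 6))
    y <- matrix(rnorm(n * 12, 5, 1), n, 12,
      dimnames = list(sprintf("g%02d", 1:n), sprintf("s%02d", 1:12))
    )
  })
  fit <- fit_weighted_lm(y, NULL, design)
  d0 <- 7.3
  s02 <- 0.81
  tab <- ebayes_moderate(fit, coef = "group", d0 = d0, s02 = s02)
  # independent closed-form script
  d <- fit$df_residual
  s2_post <- (d0 * s02 + d * fit$sigma2) / (d0 + d)
  t_oracle <- fit$coefficients[, "group"] /
    (fit$stdev_unscaled[, "group"] * sqrt(s2_post))
  p_oracle <- 2 * pt(-abs(t_oracle), d0 + d)
  expect_equal(tab$t, unname(t_oracle), tolerance = 1e-10)
  expect_equal(tab$p_value, unname(p_oracle), tolerance = 1e-10)
  expect_equal(tab$fdr, p.adjust(unname(p_oracle), "BH"), tolerance = 1e-12)
})

test_that("equal variances collapse to the pooled-variance t", {
  design <- cbind(intercept = 1, group = rep(c(0, 1), each = 5))
  withr::with_seed(10, {
    base <- rnorm(10)
  })
  # every gene = same values shifted, so all residual variances are equal
  y <- t(sapply(1:20, function(i) base + i))
  dimnames(y) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10))
  fit <- fit_weighted_lm(y, NULL, design)
  expect_equal(var(fit$sigma2), 0, tolerance = 1e-20)
  tab <- ebayes_moderate(fit, coef = "group")
  expect_true(is.infinite(attr(tab, "d0")))
  pooled_t <- fit$coefficients[, "group"] /
    (fit$stdev_unscaled[, "group"] * sqrt(mean(fit$sigma2)))
  expect_equal(tab$t, unname(pooled_t), tolerance = 1e-6)
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  fx <- de_fixture(n_genes = 300, seed = 11)
  design <- build_design(fx$samples)
  vw <- voom_weights(fx$counts, design, normalize = FALSE)
  fit <- fit_weighted_lm(vw$logcpm, vw$weights, design)
  tab <- ebayes_moderate(fit, coef = "group")

  ref_fit <- limma::lmFit(vw$logcpm, design, weights = vw$weights)
  ref <- limma::eBayes(ref_fit)
  expect_equal(tab$lfc, unname(ref$coefficients[, "group"]), tolerance = 1e-8)
  expect_equal(attr(tab, "d0"), ref$df.prior, tolerance = 1e-4)
  expect_equal(attr(tab, "s02"), ref$s2.prior, tolerance = 1e-4)
  expect_equal(tab$t, unname(ref$t[, "group"]), tolerance = 1e-6)
  expect_equal(tab$p_value, unname(ref$p.value[, "group"]), tolerance = 1e-6)
})

test_that("null simulation controls type-I error", {
  withr::with_seed(20, {
    counts <- matrix(rnbinom(2000 * 16, mu = 2^rnorm(2000 * 16, 6, 1), size = 10),
      2000, 16,
      dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:16))
    )
  })
  samples <- tibble::tibble(
    sample_id = colnames(counts),
    cohort = rep(c("tumor", "cell_line"), each = 8),
    purity = c(withr::with_seed(21, rbeta(8, 5, 2)), rep(NA, 8))
  )
  tab <- differential_expression(counts, samples)
  frac <- mean(tab$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
})

test_that("DE calls respect both cutoffs and recover planted effects", {
  tab <- tibble::tibble(
    gene = c("a", "b", "c"),
    lfc = c(2.5, 2.5, -3),
    t = c(5, 5, -6),
    p_value = c(1e-5, 1e-3, 1e-6),
    fdr = c(0.005, 0.02, 0.001)
  )
  called <- call_de(tab)
  expect_equal(called$de, c(TRUE, FALSE, TRUE))
  expect_equal(called$direction, c("up_in_tumor", "up_in_tumor", "up_in_cell_line"))

  fx <- de_fixture(n_genes = 1000, n_planted = 100, lfc = 4, n_per = 15,
    seed = 30
  )
  res <- differential_expression(fx$counts, fx$samples)
  found <- res$gene[res$de & res$direction == "up_in_tumor"]
  expect_gte(length(intersect(found, fx$planted)), 90)
  # false positives stay rare
  expect_lte(length(setdiff(found, fx$planted)), 10)
})

test_that("flipping group coding flips every LFC sign exactly", {
  fx <- de_fixture(n_genes = 200, seed = 12)
  design <- build_design(fx$samples)
  vw <- voom_weights(fx$counts, design, normalize = FALSE)
  fit <- fit_weighted_lm(vw$logcpm, vw$weights, design)
  tab <- ebayes_moderate(fit, "group")

  design_f <- design
  design_f[, "group"] <- 1 - design_f[, "group"]
  fit_f <- fit_weighted_lm(vw$logcpm, vw$weights, design_f)
  tab_f <- ebayes_moderate(fit_f, "group")
  expect_equal(tab$lfc, -tab_f$lfc, tolerance = 1e-10)
  expect_equal(tab$p_value, tab_f$p_value, tolerance = 1e-10)
})

test_that("BH thresholding is monotone in p", {
  fx <- de_fixture(seed = 13)
  res <- differential_expression(fx$counts, fx$samples)
  flagged <- res$fdr < 0.01 # FDR thresholding alone (the LFC rule is separate)
  if (any(flagged) && any(!flagged)) {
    expect_lt(max(res$p_value[flagged]), min(res$p_value[!flagged]) + 1e-12)
  }
  ord <- order(res$p_value)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
})

test_that("consistent-gene counting matches the binomial-tail oracle", {
  # gene DE in 20/20 types is included at min_types = 20; 19/20 is not
  mk_tab <- function(de_genes) {
    tibble::tibble(
      gene = sprintf("g%02d", 1:20),
      lfc = 3, t = 5, p_value = 1e-5, fdr = 1e-4,
      de = sprintf("g%02d", 1:20) %in% de_genes,
      direction = "up_in_tumor"
    )
  }
  tabs <- c(
    replicate(19, mk_tab(c("g01", "g02")), simplify = FALSE),
    list(mk_tab("g01"))
  )
  expect_equal(consistent_genes(tabs, 20), "g01")
  expect_setequal(consistent_genes(tabs, 19), c("g01", "g02"))

  # random flags at rate q: expected hit count matches the binomial tail
  q <- 0.3
  n_types <- 8
  min_t <- 5
  n_genes <- 600
  sim <- withr::with_seed(31, {
    tabs_r <- lapply(seq_len(n_types), function(i) {
      de <- runif(n_genes) < q
      tibble::tibble(
        gene = sprintf("g%03d", seq_len(n_genes)),
        lfc = 3, t = 5, p_value = 0.001, fdr = 0.001,
        de = de, direction = "up_in_tumor"
      )
    })
    length(consistent_genes(tabs_r, min_t))
  })
  expected <- n_genes * sum(stats::dbinom(min_t:n_types, n_types, q))
  sd_bin <- sqrt(expected) # Poisson-scale simulation error
  expect_lt(abs(sim - expected), 4 * sd_bin + 5)
})
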