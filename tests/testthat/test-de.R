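toy_em <- function(M, orientation, batch = NULL) {
  ma <- lapply(seq_len(ncol(M)), function(j) {
    ok <- !is.na(M[, j])
    data.frame(probe_id = rownames(M)[ok], M = M[ok, j],
               A = 10, x = 1, y = 1, stringsAsFactors = FALSE)
  })
  expression_matrix(ma, orientation, batch)
}

test_that("orientation-corrected means, variances, dfs match hand arithmetic", {
  # spreadsheet-style oracle for a 4-array toy matrix
  M <- rbind(g1 = c(0.5, -0.5, 0.4, -0.6),
             g2 = c(0.0, 0.0, 0.0, 0.0),
             g3 = c(1.0, -1.2, NA, -0.8))
  orient <- c(1, -1, 1, -1)
  em <- toy_em(M, orient)
  fit <- dyeswap_fit(em, moderate = FALSE)
  tab <- fit$table[match(c("g1", "g2", "g3"), fit$table$gene_id), ]

  # g1 corrected: 0.5, 0.5, 0.4, 0.6 -> mean 0.5, var 1/150, df 3
  expect_equal(tab$log2FC[1], 0.5)
  expect_equal(tab$s2[1], var(c(0.5, 0.5, 0.4, 0.6)))
  expect_equal(tab$df[1], 3)
  expect_equal(tab$median_log2FC[1], 0.5)
  # g2 all zero
  expect_equal(tab$log2FC[2], 0)
  # g3 corrected: 1.0, 1.2, 0.8 -> mean 1.0, df 2, n = 3
  expect_equal(tab$log2FC[3], 1.0)
  expect_equal(tab$df[3], 2)
  expect_equal(tab$n_arrays[3], 3)

  # two-array minimal case: M = +0.5 at +1 and -0.5 at -1
  M2 <- rbind(g1 = c(0.5, -0.5))
  fit2 <- dyeswap_fit(toy_em(M2, c(1, -1)), moderate = FALSE)
  expect_equal(fit2$table$log2FC, 0.5)
})

test_that("without moderation the statistic is the ordinary one-sample t", {
  set.seed(9)
  M <- matrix(rnorm(40), 10, 4,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  em <- toy_em(M, c(1, -1, 1, -1))
  fit <- dyeswap_fit(em, moderate = FALSE)
  corrected <- sweep(M, 2, c(1, -1, 1, -1), `*`)
  for (i in 1:10) {
    tt <- t.test(corrected[i, ])
    expect_equal(fit$table$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(fit$table$p[i], tt$p.value, tolerance = 1e-12)
  }
})

test_that("moment matching recovers a known variance prior", {
  set.seed(31)
  n <- 2000; d0 <- 4; s0_2 <- 0.01; dg <- 6
  # s^2 ~ s0^2 * (chisq_dg / dg) / (chisq_d0 / d0) = s0^2 * F(dg, d0)
  s2 <- s0_2 * rf(n, dg, d0)
  mod <- moderate_variances(s2, rep(dg, n))
  expect_lt(abs(mod$d0 - d0) / d0, 0.5)
  expect_lt(abs(mod$s0_2 - s0_2) / s0_2, 0.25)
  # posterior is the df-weighted compromise
  expect_equal(mod$s2_post,
               (mod$d0 * mod$s0_2 + dg * s2) / (mod$d0 + dg),
               tolerance = 1e-12)
})

test_that("moderation agrees with the reference empirical-Bayes fit", {
  set.seed(77)
  s2 <- 0.02 * rf(500, 8, 5)
  mod <- moderate_variances(s2, rep(8, 500))
  ref <- limma::squeezeVar(s2, df = 8)
  expect_equal(mod$d0, ref$df.prior, tolerance = 0.02)
  expect_equal(mod$s0_2, ref$var.prior, tolerance = 0.02)
  expect_equal(mod$s2_post, ref$var.post, tolerance = 0.02)
})

test_that("equal variances collapse to the pooled (unshrunk) value", {
  s2 <- rep(0.04, 50)
  expect_warning(mod <- moderate_variances(s2, rep(5, 50)), "pooled")
  expect_equal(mod$s2_post, s2)
  expect_identical(mod$d0, Inf)
  expect_error(moderate_variances(rep(0.1, 5), rep(3, 5)),
               class = "poe_data_error")
})

test_that("BH q values follow the step-up rule and are monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(2)
  p <- sort(runif(100))
  expect_true(all(diff(bh_fdr(p)) >= 0))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "poe_data_error")
})

test_that("BH controls the null false-positive fraction", {
  hits <- 0; total <- 0
  for (seed in 1:4) {
    set.seed(seed)
    M <- matrix(rnorm(1500 * 6, 0, 0.3), 1500, 6,
                dimnames = list(sprintf("g%04d", 1:1500), NULL))
    em <- toy_em(M, rep(c(1, -1), 3))
    fit <- dyeswap_fit(em)
    hits <- hits + sum(fit$table$q < 0.05, na.rm = TRUE)
    total <- total + sum(!is.na(fit$table$q))
  }
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(hits / total, 0.05 + 3 * se)
})

test_that("sign-flip permutation FDR is calibrated and deterministic", {
  set.seed(13)
  M <- matrix(rnorm(2000 * 8, 0, 0.3), 2000, 8,
              dimnames = list(sprintf("g%04d", 1:2000), NULL))
  em <- toy_em(M, rep(c(1, -1), 4))
  pf <- permutation_fdr(em, n_perm = 200, seed = 5)
  # pure null: at the observed 95th percentile of |t| the FDR is ~1
  thr <- quantile(abs(pf$stat), 0.95, na.rm = TRUE)
  at_thr <- pf$perm_fdr[which.min(abs(abs(pf$stat) - thr))]
  expect_gt(at_thr, 0.85)

  pf2 <- permutation_fdr(em, n_perm = 200, seed = 5)
  expect_identical(pf, pf2)
  expect_error(permutation_fdr(em, n_perm = 5), class = "poe_data_error")

  # strong planted signal in 10% of genes: FDR near zero at their weakest |t|
  M2 <- M
  planted <- 1:200
  M2[planted, ] <- M2[planted, ] + rep(c(1, -1), 4)[col(M2[planted, ])] * 3
  em2 <- toy_em(M2, rep(c(1, -1), 4))
  pf3 <- permutation_fdr(em2, n_perm = 200, seed = 5)
  weakest <- min(abs(pf3$stat[planted]))
  expect_lt(pf3$perm_fdr[which(abs(pf3$stat) == weakest)], 0.05)
})

test_that("fit object methods expose coefficients, residuals and summary", {
  sim <- small_experiment()
  ma <- suppressWarnings(lapply(sim$hybridizations, function(h) {
    normalize_hybridization(filter_hybridization(h)$hyb)
  }))
  em <- expression_matrix(ma, sim$truth$orientation, sim$truth$batch)
  fit <- dyeswap_fit(em)
  expect_s3_class(fit, "dyeswap_fit")
  co <- coef(fit)
  expect_named(co)
  expect_equal(unname(co), fit$table$log2FC)
  r <- residuals(fit)
  expect_equal(rowMeans(r, na.rm = TRUE), rep(0, nrow(r)),
               ignore_attr = TRUE, tolerance = 1e-10)
  s <- summary(fit)
  expect_s3_class(s, "summary.dyeswap_fit")
  expect_output(print(fit), "prior df")
  expect_gt(fit$d0, 0)
  expect_true(is.finite(fit$batch_concordance))
})
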