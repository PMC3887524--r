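test_that("sample odds ratios and Fisher P values match printed tables", {
  all_genes <- contingency_test(161, 1103, 205, 1002)
  expect_equal(round(all_genes$or, 2), 0.71)
  expect_equal(round(all_genes$p_value, 4), 0.0032)

  excl <- contingency_test(38, 308, 141, 722)
  expect_equal(round(excl$or, 2), 0.63)
  expect_equal(round(excl$p_value, 4), 0.0196)

  yellow <- contingency_test(10, 126, 57, 265)
  expect_equal(round(yellow$or, 2), 0.37)
  expect_equal(round(yellow$p_value, 4), 0.0036)

  # degenerate column: odds ratio undefined, P still computable
  testis <- contingency_test(80, 495, 0, 10)
  expect_true(is.na(testis$or))
  expect_equal(round(testis$p_value, 3), 0.372)

  flat <- contingency_test(5, 5, 5, 5)
  expect_equal(flat$or, 1)
  expect_equal(flat$p_value, 1)
  expect_error(contingency_test(-1, 2, 3, 4), class = "poe_data_error")
})

test_that("odds ratio and Fisher P have their symmetries", {
  t0 <- contingency_test(12, 5, 7, 30)
  # swapping both rows and both columns leaves the OR unchanged
  t1 <- contingency_test(30, 7, 5, 12)
  expect_equal(t1$or, t0$or)
  # transposition leaves the Fisher P unchanged
  t2 <- contingency_test(12, 7, 5, 30)
  expect_equal(t2$p_value, t0$p_value)
})

test_that("goodness-of-fit chi-square matches the direct formula", {
  exact <- chisq_gof(c(50, 50), c(0.5, 0.5))
  expect_equal(exact$chisq, 0)
  expect_equal(exact$p_value, 1)

  g1 <- chisq_gof(c(60, 40), c(0.5, 0.5))
  expect_equal(g1$chisq, 4)
  expect_equal(g1$p_value, pchisq(4, 1, lower.tail = FALSE))

  # X-linked deficit among 2480 mapped DE genes vs 16.801% background
  p_x <- 0.16801
  g2 <- chisq_gof(c(366, 2114), c(p_x, 1 - p_x))
  expect_equal(g2$chisq, 7.4047, tolerance = 1e-4)
  expect_equal(g2$p_value, 0.00651, tolerance = 1e-3)
  # the continuity-corrected variant lands on the printed 0.007
  g3 <- chisq_gof(c(366, 2114), c(p_x, 1 - p_x), correct = TRUE)
  expect_equal(round(g3$p_value, 3), 0.007)

  expect_error(chisq_gof(c(10, 10), c(0.6, 0.6)), class = "poe_data_error")
  expect_error(chisq_gof(c(10, 10), c(1, 0)), class = "poe_data_error")
})

test_that("Mann-Whitney agrees with brute-force enumeration on small sets", {
  g <- c(1, 2, 3); r <- c(4, 5, 6)
  res <- mannwhitney_shift(g, r)
  expect_equal(res$U, 0)
  # oracle: enumerate all 20 assignments of ranks to the first group and
  # count those with U as or more extreme (two-sided)
  pool <- c(g, r)
  combs <- combn(6, 3)
  u_of <- function(idx) {
    a <- pool[idx]; b <- pool[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_all <- apply(combs, 2, u_of)
  u_obs <- u_of(1:3)
  p_exact <- mean(pmin(u_all, 9 - u_all) <= min(u_obs, 9 - u_obs))
  expect_equal(res$p_value, p_exact)   # = 0.1
  expect_equal(p_exact, 0.1)

  same <- mannwhitney_shift(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$median_diff, 0)
  shifted <- mannwhitney_shift(c(1, 2, 9) + 0.5, c(1, 2, 9))
  expect_equal(shifted$median_diff, 0.5)
  expect_error(mannwhitney_shift(numeric(0), r), class = "poe_data_error")
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10))$rho, -1)
  r <- spearman_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$rho, 0.6)
  n <- 4; tv <- 0.6 * sqrt((n - 2) / (1 - 0.36))
  expect_equal(r$p_value, 2 * pt(tv, 2, lower.tail = FALSE))
  expect_error(spearman_corr(rep(1, 5), 1:5), class = "poe_data_error")
  expect_error(spearman_corr(1:2, 1:2), class = "poe_data_error")
})

test_that("SMA slope is the sd ratio with the correlation's sign", {
  perfect <- sma_fit(1:10, 2 * (1:10))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$intercept, 0)

  ex <- sma_fit(c(0, 1, 2), c(1, 3, 4))
  expect_equal(round(ex$slope, 4), 1.5275)  # sd(y)/sd(x) = sqrt(7/3)

  # identity: SMA slope = geometric mean of y-on-x slope and 1/(x-on-y slope)
  set.seed(8)
  x <- rnorm(50); y <- 1.7 * x + rnorm(50, 0, 0.5)
  s <- sma_fit(x, y)
  b_yx <- unname(coef(lm(y ~ x))[2])
  b_xy <- unname(coef(lm(x ~ y))[2])
  expect_equal(abs(s$slope), sqrt(abs(b_yx / b_xy)), tolerance = 1e-10)

  # negative association flips the sign
  sneg <- sma_fit(x, -y)
  expect_equal(sneg$slope, -s$slope, tolerance = 1e-10)
  expect_error(sma_fit(rep(1, 5), 1:5), class = "poe_data_error")
})

test_that("chromosome tables use mapped-only percentage denominators", {
  # annotation shaped like the observed all-spot arm distribution
  counts_all <- c(X = 2719, `2L` = 2992, `2R` = 3225, `3L` = 3235,
                  `3R` = 3915, `4` = 98, Other = 514)
  counts_de <- c(X = 366, `2L` = 505, `2R` = 518, `3L` = 511,
                 `3R` = 571, `4` = 9, Other = 55)
  ann <- data.frame(
    gene_id = sprintf("g%05d", seq_len(sum(counts_all))),
    arm = rep(names(counts_all), counts_all),
    stringsAsFactors = FALSE
  )
  de <- unlist(lapply(names(counts_de), function(a) {
    ann$gene_id[ann$arm == a][seq_len(counts_de[[a]])]
  }))
  tab <- chromosome_table(de, ann$gene_id, ann)
  expect_equal(round(tab$pct_all[tab$arm == "X"], 1), 16.8)
  expect_equal(round(tab$pct_de[tab$arm == "X"], 1), 14.8)
  expect_equal(round(tab$pct_de[tab$arm == "2L"], 1), 20.4)
  expect_equal(sum(tab$pct_all, na.rm = TRUE), 100, tolerance = 0.1)
  expect_equal(sum(tab$pct_de, na.rm = TRUE), 100, tolerance = 0.1)
  # the X deficit is flagged after BH adjustment across the six arms
  expect_true(tab$flag[tab$arm == "X"])

  # a DE set equal to the background matches it everywhere, no flags
  tab0 <- chromosome_table(ann$gene_id, ann$gene_id, ann)
  expect_equal(tab0$pct_de, tab0$pct_all)
  expect_false(any(tab0$flag))

  # empty DE set: zero counts, no tests
  tabe <- chromosome_table(character(0), ann$gene_id, ann)
  expect_true(all(tabe$n_de == 0))
  expect_true(all(is.na(tabe$p)))
})

test_that("direction bias reports binomial and Fisher evidence", {
  lfc <- c(rep(-1, 10), rep(1, 10), rep(-0.5, 5), rep(0.5, 5))
  sig <- rep(c(TRUE, FALSE), c(20, 10))
  cls <- rep(c(TRUE, FALSE), c(10, 20))  # all class members down
  db <- direction_bias(lfc, sig, cls)
  expect_equal(db$n_down, 10)
  expect_equal(db$p_value, 2 * 0.5^10)
  expect_equal(db$statistic, 1)

  even <- direction_bias(c(rep(-1, 5), rep(1, 5)), rep(TRUE, 10),
                         rep(TRUE, 10))
  expect_equal(even$p_value, 1)

  none <- direction_bias(lfc, sig, rep(FALSE, 30))
  expect_true(is.na(none$p_value))
  expect_equal(none$n_class, 0L)
})
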