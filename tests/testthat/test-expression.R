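# Relative expression, group comparisons, correlation and reporter
# normalisation.

test_that("2^-ddCt follows the Livak formula and its invariances", {
  expect_equal(relative_expression(25, 20, 24, 21)$value, 0.25)
  expect_equal(relative_expression(23, 23, 23, 23)$value, 1)
  expect_error(relative_expression(Inf, 20, 24, 21), "finite")

  # shift invariance: adding a constant to every Ct leaves 2^-ddCt alone
  set.seed(31)
  for (i in 1:20) {
    ct <- runif(4, 15, 30)
    c0 <- runif(1, -5, 5)
    expect_equal(relative_expression(ct[1] + c0, ct[2] + c0,
                                     ct[3] + c0, ct[4] + c0)$value,
                 relative_expression(ct[1], ct[2], ct[3], ct[4])$value)
  }
})

test_that("Mann-Whitney p is exact for small samples", {
  # same multiset in both groups carries zero evidence
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # full separation of 5 vs 5: the two most extreme of C(10,5) orderings
  expect_equal(compare_groups(1:5, 6:10)$p_value, 2 / 252)
  expect_error(compare_groups(numeric(0), 1:3), "non-empty")
})

test_that("tied small-sample Mann-Whitney matches permutation enumeration", {
  set.seed(91)
  for (i in 1:12) {
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    a <- sample(1:3, na, replace = TRUE)  # heavy ties by construction
    b <- sample(1:3, nb, replace = TRUE)
    expect_equal(compare_groups(a, b)$p_value, mw_permutation_p(a, b),
                 tolerance = 1e-9)
  }
})

test_that("group comparisons are symmetric and the t-test matches closed form", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1))
    expect_equal(compare_groups(a, b)$p_value, compare_groups(b, a)$p_value)
  }

  a <- c(0.8, 0.7, 0.75); b <- c(1.0, 1.05, 0.95)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  tstat <- (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  p_hand <- 2 * pt(-abs(tstat), df = length(a) + length(b) - 2)
  expect_equal(compare_groups(a, b, method = "t_test")$p_value, p_hand)
})

test_that("Spearman correlation is rank-based and reports rho and rho^2", {
  x <- c(0.1, 0.5, 1.2, 2.5, 3.1)
  r <- correlate_genes(x, exp(x))
  expect_equal(r$rho, 1)
  expect_equal(r$r_squared, 1)
  expect_equal(correlate_genes(x, -x)$rho, -1)
  expect_equal(correlate_genes(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_error(correlate_genes(c(1, 1, 1), c(1, 2, 3)), "constant")

  # invariance under strictly increasing transforms
  set.seed(6)
  for (i in 1:10) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(correlate_genes(exp(x), y)$rho, correlate_genes(x, y)$rho)
  }
})

test_that("reporter activity normalises firefly/Renilla ratios to control", {
  same <- reporter_activity(c(2, 3, 4), c(2, 3, 4), c(1, 1, 1))
  expect_equal(same$relative_activity, 1)

  r1 <- reporter_activity(c(2, 3, 4), c(1, 1, 1), c(1, 1.1, 0.9))
  r2 <- reporter_activity(c(2, 3, 4), c(2, 2, 2), c(1, 1.1, 0.9))
  expect_equal(r2$relative_activity, r1$relative_activity / 2)
  expect_error(reporter_activity(c(1, 2), c(1, 0), c(1)), "positive")

  test_r <- c(0.8, 0.7, 0.75); ctrl <- c(1.0, 1.05, 0.95)
  res <- reporter_activity(test_r, rep(1, 3), ctrl)
  expect_equal(res$p_value,
               compare_groups(test_r, ctrl, method = "t_test")$p_value)
  expect_identical(res$n_replicates, 3L)
})

test_that("the full expression analysis handles pairing and edge cases", {
  # a single pair with identical tumor/normal Cts gives fold change 1
  tab <- expand.grid(sample = "S1", gene = c("G1", "G3", "HPRT1"),
                     tissue = c("tumor", "normal"), replicate = 1:2,
                     stringsAsFactors = FALSE)
  tab$ct <- ifelse(tab$gene == "HPRT1", 20, 24)
  res <- run_expression_analysis(tab, c("G1", "G3"))
  expect_equal(res$per_pair$rel_expr, c(1, 1))

  # an incomplete pair is dropped with a warning, not an error
  spec <- expression_sim_spec(
    4, data.frame(gene = "G1", delta = 1, loading = 0), seed = 2)
  full <- simulate_paired_ct(spec)
  broken <- full[!(full$sample == "S001" & full$tissue == "tumor"), ]
  expect_warning(res2 <- run_expression_analysis(broken, "G1"), "S001")
  expect_identical(res2$per_gene$n_pairs, 3L)

  expect_error(run_expression_analysis(full, "G1", ref_gene = "TBP"),
               "TBP")
})

test_that("tumor downregulation is detected and the null is calibrated locally", {
  spec <- expression_sim_spec(
    27, data.frame(gene = c("G1", "G3"), delta = c(1.5, 1.5),
                   loading = c(1, 1)), seed = 19)
  res <- run_expression_analysis(simulate_paired_ct(spec), c("G1", "G3"))
  expect_true(all(res$per_gene$p_value < 0.05))
  expect_true(all(res$per_gene$median_rel_expr < 1))
  expect_gt(res$correlations$rho, 0)
  expect_equal(res$correlations$r_squared, res$correlations$rho^2)
})
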