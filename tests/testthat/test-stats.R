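test_that("variance gate reproduces the pooled/Welch mix implied by the cohort table", {
  ref <- cohort_summaries("alps")
  dur <- group_summaries_of(ref, "duration")
  hy <- group_summaries_of(ref, "hy")
  # duration: F = 3.65^2/2.38^2 = 2.35 on (20, 46) df, two-sided p < 0.05
  gd <- variance_gate(dur$pd_a, dur$pd_na)
  expect_equal(gd$statistic, 3.65^2 / 2.38^2, tolerance = 1e-12)
  expect_lt(gd$p, 0.05)
  expect_equal(gd$variant, "welch")
  # H&Y: F = 1.25, not significant -> pooled
  gh <- variance_gate(hy$pd_a, hy$pd_na)
  expect_equal(gh$variant, "pooled")
  # equal SDs -> F = 1 -> pooled
  a <- group_summary("a", 10, 0, 1); b <- group_summary("b", 12, 0, 1)
  expect_equal(variance_gate(a, b)$statistic, 1)
  expect_equal(variance_gate(a, b)$variant, "pooled")
})

test_that("t and F from summaries agree with the raw-data routes to 1e-10", {
  set.seed(41)
  x <- rnorm(21, 5.6, 3.6); y <- rnorm(47, 3.4, 2.4); z <- rnorm(38, 3, 2)
  sx <- summarize_group(x, "x"); sy <- summarize_group(y, "y")
  for (variant in c("pooled", "welch")) {
    raw <- t_test_groups(x, y, variant = variant)
    summ <- t_test_groups(sx, sy, variant = variant)
    expect_equal(raw$statistic, summ$statistic, tolerance = 1e-10)
    expect_equal(raw$df, summ$df, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
  }
  fr <- anova_oneway(list(x = x, y = y, z = z))
  fs <- anova_oneway(list(summarize_group(x, "x"), summarize_group(y, "y"),
                          summarize_group(z, "z")))
  expect_equal(fr$statistic, fs$statistic, tolerance = 1e-10)
  expect_equal(fr$p, fs$p, tolerance = 1e-10)
})

test_that("degenerate group comparisons behave as identities", {
  a <- group_summary("a", 20, 3.2, 1.1)
  expect_equal(t_test_groups(a, a, variant = "pooled")$statistic, 0)
  expect_equal(t_test_groups(a, a, variant = "pooled")$p, 1)
  # equal group means -> F = 0
  gs <- list(group_summary("a", 10, 2, 1), group_summary("b", 15, 2, 1.3),
             group_summary("c", 12, 2, 0.8))
  expect_equal(anova_oneway(gs)$statistic, 0)
  expect_error(anova_oneway(list(a)), "two groups")
  expect_error(group_summary("a", 1, 0, 1), ">= 2")
  expect_error(group_summary("a", 5, 0, 0), "> 0")
})

test_that("ANOVA post-hoc pairwise tests carry Bonferroni-corrected p-values", {
  ref <- cohort_summaries("alps")
  res <- anova_oneway(group_summaries_of(ref, "hama"), pairwise = TRUE)
  pw <- res$pairwise
  expect_equal(nrow(pw), 3L)
  expect_equal(pw$p_bonferroni, pmin(1, 3 * pw$p))
  # enormous HAMA separation: PD-A vs both other groups significant
  expect_lt(max(pw$p_bonferroni[pw$group1 == "pd_a" | pw$group2 == "pd_a"]),
            1e-6)
})

test_that("chi-square matches hand-computed Pearson X^2 and rejects zero margins", {
  tab <- rbind(c(10, 11), c(30, 17), c(19, 19))
  res <- chi_square_test(tab)
  # independent oracle: sum (O - E)^2 / E with E from the margins
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)
  expect_equal(res$df, 2)
  # table equal to its expected values -> X^2 = 0
  expect_equal(chi_square_test(E)$statistic, 0, tolerance = 1e-12)
  expect_error(chi_square_test(rbind(c(0, 0), c(3, 4))), "marginal")
})

test_that("Kruskal-Wallis reproduces the hand-ranked example and its null distribution", {
  res <- kruskal_wallis_test(list(1:3, 4:6, 7:9))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_error(kruskal_wallis_test(list(rep(1, 5), rep(1, 4))), "tied")
  # permuted labels: H ~ chi-square(2)
  set.seed(51)
  vals <- rnorm(24)
  H <- replicate(1000, {
    idx <- sample(24)
    kruskal_wallis_test(list(vals[idx[1:8]], vals[idx[9:16]],
                             vals[idx[17:24]]))$statistic
  })
  expect_gt(suppressWarnings(ks.test(H, "pchisq", df = 2))$p.value, 0.01)
})

test_that("Bonferroni correction is the capped multiple of p", {
  expect_equal(bonferroni_pairwise(0.01, m = 3), 0.03)
  expect_equal(bonferroni_pairwise(0.5, m = 3), 1)
  expect_equal(bonferroni_pairwise(c(0.2, 0.7), m = 1), c(0.2, 0.7))
  # monotone
  p <- sort(runif(10))
  expect_true(all(diff(bonferroni_pairwise(p, m = 4)) >= 0))
  expect_error(bonferroni_pairwise(1.2), "\\[0, 1\\]")
})

test_that("partial correlation by residualization matches the recursive formula", {
  # 5-point worked example, one covariate
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 7)
  z <- c(1, 3, 2, 5, 4)
  got <- partial_correlation(x, y, cbind(z = z))
  expect_equal(got$r, oracle_partial_r(x, y, z), tolerance = 1e-12)
  expect_equal(got$df, 2)
  # y = x + covariate exactly: the two routes still agree
  y2 <- x + z
  expect_equal(partial_correlation(x, y2, cbind(z = z))$r,
               oracle_partial_r(x, y2, z), tolerance = 1e-12)
  # no covariates reduces to plain Pearson
  set.seed(61)
  u <- rnorm(30); v <- rnorm(30)
  expect_equal(partial_correlation(u, v)$r, cor(u, v), tolerance = 1e-12)
  expect_equal(partial_correlation(u, v)$p, cor.test(u, v)$p.value,
               tolerance = 1e-10)
  expect_error(partial_correlation(u, v, cbind(a = 1:30, b = 2 * (1:30))),
               "rank-deficient")
})

test_that("Pearson correlation handles exact affine relations and calibrates under the null", {
  x <- c(0.3, 1.2, 2.5, 3.1, 4.8)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 5)), "variance")
  set.seed(71)
  pvals <- replicate(1000, pearson_correlation(rnorm(86), rnorm(86))$p)
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
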