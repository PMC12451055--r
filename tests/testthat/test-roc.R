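test_that("AUC matches the exhaustive pair-count oracle, including ties", {
  set.seed(91)
  for (rep in 1:20) {
    scores <- sample(1:8, 30, replace = TRUE)     # many ties
    labels <- sample(c(TRUE, FALSE), 30, replace = TRUE, prob = c(.4, .6))
    if (!any(labels) || all(labels)) next
    got <- roc_auc(scores, labels, direction = ">")
    expect_equal(got$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  }
  # the spec's worked case: {1,2,3,4} with one tie added
  s <- c(1, 2, 2, 3); y <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(s, y, direction = ">")$auc, oracle_auc(s, y))
  expect_equal(oracle_auc(s, y), 0.875)
})

test_that("AUC is invariant under monotone transforms and flips under negation", {
  set.seed(92)
  scores <- rnorm(40)
  labels <- rep(c(TRUE, FALSE), each = 20)
  a <- roc_auc(scores, labels, direction = ">")$auc
  expect_equal(roc_auc(exp(scores), labels, direction = ">")$auc, a)
  expect_equal(roc_auc(rank(scores), labels, direction = ">")$auc, a)
  expect_equal(roc_auc(-scores, labels, direction = ">")$auc, 1 - a,
               tolerance = 1e-12)
  # auto direction gives AUC >= 0.5 and records the orientation
  r1 <- roc_auc(scores, labels, direction = "auto")
  r2 <- roc_auc(-scores, labels, direction = "auto")
  expect_gte(r1$auc, 0.5)
  expect_equal(r1$auc, r2$auc)
  expect_false(r1$direction == r2$direction)
})

test_that("perfect separation and the null both behave as expected", {
  y <- rep(c(TRUE, FALSE), each = 10)
  s <- c(rnorm(10, 10), rnorm(10, 0))
  r <- roc_auc(s, y, direction = ">")
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # labels independent of scores, large n -> AUC ~ 0.5
  set.seed(93)
  r0 <- roc_auc(rnorm(4000), rep(c(TRUE, FALSE), 2000), direction = ">")
  expect_lt(abs(r0$auc - 0.5), 0.05)
  expect_error(roc_auc(rnorm(5), rep(TRUE, 5)), "both classes")
})

test_that("Youden point matches the exhaustive threshold scan and prefers specificity on ties", {
  set.seed(94)
  for (rep in 1:10) {
    scores <- round(rnorm(6), 1)
    labels <- sample(c(TRUE, FALSE), 6, replace = TRUE)
    if (sum(labels) < 2 || sum(!labels) < 2) next
    got <- youden_point(roc_auc(scores, labels, direction = ">")$curve)
    want <- oracle_youden(scores, labels)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$sensitivity, want$sensitivity)
    expect_equal(got$specificity, want$specificity)
  }
  # single possible threshold
  got1 <- youden_point(data.frame(threshold = 0.5, sensitivity = 0.7,
                                  specificity = 0.6))
  expect_equal(got1$threshold, 0.5)
})

test_that("DeLong variance and comparison agree with the independent pROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(95)
  y <- rep(c(1, 0), c(16, 36))
  a <- c(rnorm(16, 1), rnorm(36))
  b <- 0.5 * a + c(rnorm(16, 0.5), rnorm(36))
  ra <- roc_auc(a, y, positive = "1", direction = ">")
  proc_a <- pROC::roc(y, a, direction = "<", quiet = TRUE)
  expect_equal(ra$auc, as.numeric(pROC::auc(proc_a)), tolerance = 1e-12)
  expect_equal(ra$var, pROC::var(proc_a), tolerance = 1e-10)
  ci <- pROC::ci.auc(proc_a, method = "delong")
  expect_equal(ra$ci95, as.numeric(ci[c(1, 3)]), tolerance = 1e-8)
  dl <- delong_test(a, b, y, positive = "1")
  proc_t <- pROC::roc.test(proc_a, pROC::roc(y, b, direction = "<", quiet = TRUE),
                           method = "delong", paired = TRUE)
  expect_equal(dl$p, proc_t$p.value, tolerance = 1e-10)
})

test_that("self-comparison yields z = 0, p = 1", {
  y <- rep(c(1, 0), c(10, 10))
  s <- rnorm(20)
  dl <- delong_test(s, s, y, positive = "1")
  expect_equal(dl$z, 0)
  expect_equal(dl$p, 1)
})

test_that("combined score reduces to the single marker and ignores redundant predictors", {
  co <- generate_cohort(cohort_spec("coupling", seed = 96))
  pd <- droplevels(co[co$group != "hc", ])
  single <- fit_combined_score(pd, "alps_r")
  auc_single <- roc_auc(single$score, pd$group, direction = "auto")$auc
  auc_marker <- roc_auc(pd$alps_r, pd$group, direction = "auto")$auc
  expect_equal(auc_single, auc_marker, tolerance = 1e-12)
  # duplicated predictor: same AUC as one copy
  pd$alps_r2 <- pd$alps_r
  dup <- fit_combined_score(pd, c("alps_r", "alps_r2"))
  expect_equal(roc_auc(dup$score, pd$group, direction = "auto")$auc,
               auc_marker, tolerance = 1e-12)
})

test_that("separation triggers the penalized fallback with a warning", {
  d <- data.frame(group = rep(c("pd_a", "pd_na"), each = 10),
                  x = c(rnorm(10, 10), rnorm(10, -10)))
  expect_warning(fit <- fit_combined_score(d, "x"), "separation")
  expect_equal(fit$model, "ridge_logistic")
  expect_true(all(is.finite(fit$score)))
  expect_equal(roc_auc(fit$score, d$group, direction = ">")$auc, 1)
})

test_that("combined model dominates single markers on generator cohorts", {
  res <- t(vapply(1:60, function(s) {
    co <- generate_cohort(cohort_spec("coupling", seed = 9600 + s))
    pd <- droplevels(co[co$group != "hc", ])
    singles <- vapply(c("alps_l", "alps_r", "coupling"), function(m)
      roc_auc(pd[[m]], pd$group, direction = "auto")$auc, numeric(1))
    glymph <- suppressWarnings(
      fit_combined_score(pd, c("alps_l", "alps_r", "coupling")))
    full <- suppressWarnings(
      fit_combined_score(pd, c("duration", "hy", "alps_l", "alps_r",
                               "coupling")))
    c(best_single = max(singles),
      glymph = roc_auc(glymph$score, pd$group, direction = ">")$auc,
      combined = roc_auc(full$score, pd$group, direction = ">")$auc)
  }, numeric(3)))
  expect_gte(mean(res[, "combined"] >= res[, "best_single"]), 0.9)
  # qualitative ordering in the majority of runs
  expect_gt(mean(res[, "combined"] > res[, "glymph"]), 0.5)
  expect_gt(mean(res[, "glymph"] > res[, "best_single"]), 0.5)
})
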