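#' Group summary (n, mean, SD)
#'
#' Printed summary rows of a cohort table are sufficient statistics for the
#' classical t and F tests; this container lets those tests run without raw
#' data.
#'
#' @param label group name.
#' @param n group size (>= 2).
#' @param mean group mean.
#' @param sd group standard deviation (> 0).
#' @return `group_summary` object.
#' @export
group_summary <- function(label, n, mean, sd) {
  if (n < 2) stop("group size must be >= 2")
  if (sd <= 0) stop("sd must be > 0")
  structure(list(label = label, n = as.integer(n), mean = mean, sd = sd),
            class = "group_summary")
}

#' Summarize a raw sample into a group summary
#' @param x numeric vector.
#' @param label group name.
#' @return [group_summary()].
#' @export
summarize_group <- function(x, label = deparse(substitute(x))) {
  group_summary(label, length(x), mean(x), sd(x))
}

glymph_test <- function(test_name, statistic, df, p, ...) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = unname(df), p = unname(p), ...),
            class = "glymph_test")
}

#' @export
print.glymph_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n", x$test_name,
              x$statistic, paste(signif(x$df, 6), collapse = ", "), x$p))
  invisible(x)
}

#' Homoscedasticity gate for the two-sample t-test
#'
#' Two-sided F-ratio test of equal variances on group summaries; the pooled
#' t-test is used when equality is not rejected at `alpha`, otherwise Welch.
#' (A summary-statistic reconstruction: Levene-type tests need raw data.)
#'
#' @param a,b [group_summary()] objects.
#' @param alpha gate level (default 0.05).
#' @return list with `variant` ("pooled" or "welch"), `statistic` (variance
#'   ratio a/b), `df`, `p`.
#' @export
variance_gate <- function(a, b, alpha = 0.05) {
  stopifnot(inherits(a, "group_summary"), inherits(b, "group_summary"))
  f <- a$sd^2 / b$sd^2
  df <- c(a$n - 1, b$n - 1)
  p <- min(1, 2 * min(pf(f, df[1], df[2]), pf(f, df[1], df[2], lower.tail = FALSE)))
  list(variant = if (p < alpha) "welch" else "pooled",
       statistic = f, df = df, p = p)
}

t_from_summaries <- function(a, b, variant) {
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Two-sample t-test from raw data or summaries
#'
#' With `variant = "auto"` the [variance_gate()] chooses pooled vs Welch.
#' Raw vectors are handled by [stats::t.test()]; summaries by the classical
#' closed forms (the two routes agree exactly when the summaries are
#' computed from the same raw data).
#'
#' @param a,b [group_summary()] objects or raw numeric vectors.
#' @param variant "auto", "pooled" or "welch".
#' @param alpha gate level for "auto".
#' @return `glymph_test` with fields `test_name` ("t_pooled"/"t_welch"),
#'   `statistic`, `df`, `p`, and `gate` (the gate result when auto).
#' @export
t_test_groups <- function(a, b, variant = c("auto", "pooled", "welch"),
                          alpha = 0.05) {
  variant <- match.arg(variant)
  raw <- is.numeric(a) && is.numeric(b)
  sa <- if (raw) summarize_group(a, "a") else a
  sb <- if (raw) summarize_group(b, "b") else b
  stopifnot(inherits(sa, "group_summary"), inherits(sb, "group_summary"))
  gate <- NULL
  if (variant == "auto") {
    gate <- variance_gate(sa, sb, alpha)
    variant <- gate$variant
  }
  if (raw) {
    ht <- t.test(a, b, var.equal = variant == "pooled")
    out <- glymph_test(paste0("t_", variant), ht$statistic, ht$parameter,
                       ht$p.value, gate = gate)
  } else {
    ts <- t_from_summaries(sa, sb, variant)
    out <- glymph_test(paste0("t_", variant), ts$t, ts$df, ts$p, gate = gate)
  }
  out
}

#' One-way ANOVA from raw data or summaries
#'
#' Classical fixed-effects F = MS_between / MS_within; computable exactly
#' from (n, mean, sd) per group. Raw samples go through
#' [stats::oneway.test()] with `var.equal = TRUE`. Optional post-hoc:
#' pairwise pooled-variance t-tests with Bonferroni correction over all
#' pairs.
#'
#' @param groups list of [group_summary()] objects or of raw numeric
#'   vectors (>= 2 groups, each n >= 2).
#' @param pairwise if `TRUE`, add Bonferroni-corrected pairwise t-tests.
#' @return `glymph_test` with `statistic` (F), `df` (df1, df2), `p`, and
#'   optionally `pairwise` (data.frame).
#' @export
anova_oneway <- function(groups, pairwise = FALSE) {
  if (length(groups) < 2) stop("need at least two groups")
  raw <- all(vapply(groups, is.numeric, logical(1)))
  gs <- if (raw) {
    labs <- names(groups)
    if (is.null(labs)) labs <- paste0("g", seq_along(groups))
    Map(function(x, l) summarize_group(x, l), groups, labs)
  } else groups
  if (!all(vapply(gs, inherits, logical(1), "group_summary")))
    stop("groups must be group summaries or raw numeric vectors")
  n <- vapply(gs, `[[`, numeric(1), "n")
  m <- vapply(gs, `[[`, numeric(1), "mean")
  s <- vapply(gs, `[[`, numeric(1), "sd")
  k <- length(gs)
  N <- sum(n)
  if (raw) {
    values <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(seq_len(k), times = n))
    ht <- oneway.test(values ~ fac, var.equal = TRUE)
    f <- unname(ht$statistic); df <- unname(ht$parameter); p <- ht$p.value
  } else {
    grand <- sum(n * m) / N
    msb <- sum(n * (m - grand)^2) / (k - 1)
    msw <- sum((n - 1) * s^2) / (N - k)
    f <- msb / msw
    df <- c(k - 1, N - k)
    p <- pf(f, df[1], df[2], lower.tail = FALSE)
  }
  out <- glymph_test("anova_f", f, df, p)
  if (pairwise) {
    ij <- utils::combn(k, 2)
    m_comp <- ncol(ij)
    rows <- lapply(seq_len(m_comp), function(c0) {
      i <- ij[1, c0]; j <- ij[2, c0]
      ts <- t_from_summaries(gs[[i]], gs[[j]], "pooled")
      data.frame(group1 = gs[[i]]$label, group2 = gs[[j]]$label,
                 t = ts$t, df = ts$df, p = ts$p,
                 p_bonferroni = min(1, m_comp * ts$p))
    })
    out$pairwise <- do.call(rbind, rows)
  }
  out
}

#' Pearson chi-square test of a contingency table
#'
#' @param tab matrix (or table) of counts; no zero row/column margins.
#' @return `glymph_test` with X^2, df = (r-1)(c-1), p.
#' @export
chi_square_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the contingency table")
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  glymph_test("chi_square", ht$statistic, ht$parameter, ht$p.value,
              expected = ht$expected)
}

#' Kruskal-Wallis rank test
#'
#' @param groups list of raw numeric vectors (ranks are not recoverable from
#'   summary statistics).
#' @return `glymph_test` with the tie-corrected H statistic, df = k - 1 and
#'   the chi-square approximation p.
#' @export
kruskal_wallis_test <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) < 2)
    stop("H is undefined when every value is tied")
  fac <- factor(rep(seq_along(groups), times = lengths(groups)))
  ht <- kruskal.test(values, fac)
  glymph_test("kruskal_wallis", ht$statistic, ht$parameter, ht$p.value)
}

#' Bonferroni correction
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param m number of comparisons (default `length(p)`).
#' @return `min(1, m * p)` per element.
#' @export
bonferroni_pairwise <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Partial correlation by residualization
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on
#' `[1, covariates]`, with a t-based two-sided p on n - 2 - k degrees of
#' freedom. With no covariates this is the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame of covariates (e.g. sex coded
#'   0/1), or `NULL`.
#' @return `partial_corr` object: list with `r`, `df`, `p`, `n`,
#'   `covariates` (names).
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
    cn <- character(0)
  } else {
    Zm <- as.matrix(as.data.frame(covariates))
    if (!is.numeric(Zm)) stop("covariates must be numeric (code factors first)")
    if (nrow(Zm) != n) stop("covariates must have one row per observation")
    Z <- cbind(1, Zm)
    k <- ncol(Zm)
    cn <- colnames(Zm)
    if (qr(Z)$rank < ncol(Z)) stop("covariate matrix is rank-deficient")
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- lm.fit(Z, x)$residuals
  ry <- lm.fit(Z, y)$residuals
  if (sd(rx) < 1e-300 || sd(ry) < 1e-300)
    stop("zero residual variance; partial correlation undefined")
  r <- cor(rx, ry)
  df <- n - 2L - k
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  structure(list(r = r, df = df, p = 2 * pt(-abs(t), df), n = n,
                 covariates = cn),
            class = "partial_corr")
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y numeric vectors (n >= 3, non-degenerate).
#' @return list with `r`, `df`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) < 3 || length(y) != length(x)) stop("need equal-length x, y with n >= 3")
  if (sd(x) < 1e-300 || sd(y) < 1e-300) stop("zero variance")
  ht <- cor.test(x, y)
  list(r = unname(ht$estimate), df = unname(ht$parameter), p = ht$p.value,
       n = length(x))
}

#' Shapiro-Wilk normality check
#'
#' Thin reporting wrapper used when deciding between parametric and
#' rank-based comparisons on raw data.
#'
#' @param x raw numeric vector.
#' @return `glymph_test` with the W statistic and p.
#' @export
shapiro_check <- function(x) {
  ht <- stats::shapiro.test(x)
  glymph_test("shapiro_wilk", ht$statistic, NA_real_, ht$p.value)
}
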