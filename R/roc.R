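#' ROC curve and AUC with DeLong confidence interval
#'
#' AUC via the Mann-Whitney identity (ties counted 1/2). With
#' `direction = "auto"` the orientation is chosen so that AUC >= 0.5 and is
#' recorded explicitly (for the glymphatic markers, lower values indicate
#' the positive class, so auto resolves to `"<"`). The 95% CI uses the
#' DeLong placement-value variance with a normal approximation, clipped to
#' `[0, 1]`; the operating point is Youden's J.
#'
#' @param scores numeric marker or model scores.
#' @param labels binary labels (logical, 0/1, or factor with the positive
#'   class given by `positive`); both classes must be present.
#' @param direction `">"` (higher score = positive), `"<"`, or `"auto"`.
#' @param positive positive-class label when `labels` is a factor/character.
#' @param conf_level CI level (default 0.95).
#' @return `roc_result`: list with `auc`, `var` (DeLong), `ci95`,
#'   `direction`, `threshold`, `sensitivity`, `specificity`, `curve`
#'   (data.frame threshold/sensitivity/specificity on the oriented scale),
#'   `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, direction = c("auto", ">", "<"),
                    positive = "pd_a", conf_level = 0.95) {
  direction <- match.arg(direction)
  y <- as_binary_labels(labels, positive)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  if (!any(y) || all(y)) stop("both classes must be present")

  auc_of <- function(s) {
    r <- rank(s)
    m <- sum(y)
    (sum(r[y]) - m * (m + 1) / 2) / (m * sum(!y))
  }
  if (direction == "auto")
    direction <- if (auc_of(scores) >= 0.5) ">" else "<"
  s <- if (direction == ">") scores else -scores
  auc <- auc_of(s)

  v <- delong_auc_variance(s, y, oriented = TRUE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(v), 0), 1)

  curve <- roc_curve_points(s, y)
  op <- youden_point(curve)
  structure(list(auc = auc, var = v, ci95 = ci, direction = direction,
                 threshold = op$threshold, sensitivity = op$sensitivity,
                 specificity = op$specificity, curve = curve,
                 n_pos = sum(y), n_neg = sum(!y)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "AUC = %.3f (95%% CI %.3f-%.3f), direction '%s'\nYouden point: threshold %.4g, sensitivity %.3f, specificity %.3f\n",
    x$auc, x$ci95[1], x$ci95[2], x$direction, x$threshold, x$sensitivity,
    x$specificity))
  invisible(x)
}

as_binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  as.character(labels) == positive
}

# full sweep of cutpoints (midpoints between sorted unique oriented scores,
# plus +-Inf); classifier: positive if score > threshold
roc_curve_points <- function(s, y) {
  u <- sort(unique(s))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, max(u))
  pos <- s[y]; neg <- s[!y]
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t0) mean(pos > t0), numeric(1)),
    specificity = vapply(thr, function(t0) mean(neg <= t0), numeric(1)))
}

#' Youden operating point
#'
#' Threshold maximizing J = sensitivity + specificity - 1; ties resolved
#' toward the higher specificity.
#'
#' @param curve data.frame with `threshold`, `sensitivity`, `specificity`
#'   (as in `roc_result$curve`).
#' @return one-row data.frame: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_point <- function(curve) {
  if (nrow(curve) == 0) stop("empty ROC curve")
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(curve$specificity[best])]
  data.frame(threshold = curve$threshold[best],
             sensitivity = curve$sensitivity[best],
             specificity = curve$specificity[best],
             youden_j = j[best])
}

# placement values (structural components): V10 over positives, V01 over
# negatives, psi = 1, 1/2, 0 for pos > = < neg
delong_placements <- function(s, y) {
  pos <- s[y]; neg <- s[!y]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' DeLong variance of an AUC estimate
#'
#' Placement-value (structural-component) estimator:
#' var(V10)/n1 + var(V01)/n0.
#'
#' @param scores numeric scores.
#' @param labels binary labels (see [roc_auc()]).
#' @param positive positive-class label.
#' @param oriented internal: labels already logical and scores oriented.
#' @return variance of the AUC estimate.
#' @export
delong_auc_variance <- function(scores, labels, positive = "pd_a",
                                oriented = FALSE) {
  y <- if (oriented) labels else as_binary_labels(labels, positive)
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 subjects per class")
  pl <- delong_placements(scores, y)
  var(pl$v10) / sum(y) + var(pl$v01) / sum(!y)
}

#' DeLong test comparing two correlated AUCs
#'
#' Both score vectors must be measured on the same subjects. The difference
#' variance uses the placement-value covariance; a self-comparison (or any
#' degenerate zero-variance difference with equal AUCs) returns z = 0,
#' p = 1.
#'
#' @param scores_a,scores_b paired score vectors (oriented so that higher
#'   values indicate the positive class).
#' @param labels binary labels.
#' @param positive positive-class label.
#' @return list with `auc_a`, `auc_b`, `var_diff`, `z`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels, positive = "pd_a") {
  y <- as_binary_labels(labels, positive)
  if (length(scores_a) != length(y) || length(scores_b) != length(y))
    stop("paired scores must cover the same subjects")
  pa <- delong_placements(scores_a, y)
  pb <- delong_placements(scores_b, y)
  m <- sum(y); n0 <- sum(!y)
  var_diff <- (var(pa$v10) + var(pb$v10) - 2 * cov(pa$v10, pb$v10)) / m +
    (var(pa$v01) + var(pb$v01) - 2 * cov(pa$v01, pb$v01)) / n0
  d <- pa$auc - pb$auc
  if (var_diff < 1e-16) {
    if (abs(d) < 1e-12) return(list(auc_a = pa$auc, auc_b = pb$auc,
                                    var_diff = var_diff, z = 0, p = 1))
    stop("degenerate variance in the DeLong comparison")
  }
  z <- d / sqrt(var_diff)
  list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' @importFrom stats cov
NULL

#' Multivariate combined diagnostic score
#'
#' Maximum-likelihood logistic regression on standardized predictors; the
#' returned linear predictor is the combined score for ROC analysis. On
#' (quasi-)separation the fit falls back to a lightly ridge-penalized IRLS
#' with a warning. A single predictor yields a score monotone in that
#' predictor, so its ROC is unchanged.
#'
#' @param data data.frame containing the predictors and the outcome.
#' @param predictors character vector of predictor column names.
#' @param outcome outcome column name (default `"group"`).
#' @param positive positive-class label (default `"pd_a"`).
#' @param ridge_lambda penalty used by the separation fallback.
#' @return `combined_score`: list with `score` (per-subject linear
#'   predictor), `coefficients`, `labels` (logical), `model`
#'   ("logistic" or "ridge_logistic"), `predictors`.
#' @export
fit_combined_score <- function(data, predictors, outcome = "group",
                               positive = "pd_a", ridge_lambda = 1e-2) {
  if (length(predictors) < 1) stop("need at least one predictor")
  if (!all(predictors %in% names(data)))
    stop("missing predictor columns: ",
         paste(setdiff(predictors, names(data)), collapse = ", "))
  X <- as.matrix(data[, predictors, drop = FALSE])
  if (anyNA(X)) stop("missing predictor values")
  y <- as_binary_labels(data[[outcome]], positive)
  if (!any(y) || all(y)) stop("both classes must be present")
  Xs <- scale(X)
  Xd <- cbind(`(Intercept)` = 1, Xs)

  fit <- suppressWarnings(glm.fit(Xd, y, family = binomial()))
  mu <- fit$fitted.values
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0          # aliased (redundant) predictors drop out
  separated <- !fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8) ||
    any(abs(beta[-1]) > 15)
  model <- "logistic"
  if (separated) {
    warning("(quasi-)separation detected; using a ridge-penalized logistic fit")
    beta <- ridge_logistic(Xd, y, lambda = ridge_lambda)
    model <- "ridge_logistic"
  }
  structure(list(score = drop(Xd %*% beta), coefficients = beta, labels = y,
                 model = model, predictors = predictors),
            class = "combined_score")
}

# Newton/IRLS for logistic regression with an L2 penalty on the
# non-intercept coefficients; small and dependency-free, used only as the
# separation fallback.
ridge_logistic <- function(Xd, y, lambda = 1e-2, max_iter = 100,
                           tol = 1e-10) {
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(t(Xd) %*% (y - mu)) - drop(pen %*% beta)
    hess <- t(Xd) %*% (Xd * w) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(Xd)
  beta
}
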