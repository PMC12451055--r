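#' Bundled cohort summary statistics
#'
#' Group sizes, M/F counts and per-variable (mean, SD) for the
#' PD-with-anxiety (`pd_a`), PD-without-anxiety (`pd_na`, HAMA < 14) and
#' healthy-control (`hc`) groups, for the full DTI cohort (`"alps"`,
#' n = 21/47/38) and for the subset with foramen-magnum fMRI coverage used
#' in the combined analysis (`"coupling"`, n = 16/36/34). These summaries
#' parameterize the cohort simulator and are sufficient statistics for the
#' summary-based t, F and chi-square tests.
#'
#' @param reference `"alps"` or `"coupling"`.
#' @return list with `groups` (named sizes), `sex_mf` (M/F counts per
#'   group), `variables` (per variable, per group `c(mean, sd)`).
#' @export
cohort_summaries <- function(reference = c("alps", "coupling")) {
  reference <- match.arg(reference)
  path <- system.file("extdata", "cohort_summaries.yaml", package = "glymphr")
  yaml::read_yaml(path)[[reference]]
}

#' Group summaries of one variable
#'
#' @param ref a [cohort_summaries()] list.
#' @param variable variable name (e.g. `"hama"`).
#' @return named list of [group_summary()] objects, one per group carrying
#'   the variable.
#' @export
group_summaries_of <- function(ref, variable) {
  v <- ref$variables[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  out <- lapply(names(v), function(g)
    group_summary(g, ref$groups[[g]], v[[g]][1], v[[g]][2]))
  names(out) <- names(v)
  out
}

#' Specify a synthetic cohort
#'
#' Subjects are drawn per group from normal distributions with the bundled
#' (or overridden) means/SDs; sex is Bernoulli with the group's printed M/F
#' proportion. Within each group the glymphatic markers are coupled to the
#' HAMA score through a shared Gaussian factor whose loading is calibrated,
#' in closed form from the mixture moments over the two PD groups, so that
#' the population partial correlation between marker and HAMA given the five
#' standard covariates (age, sex, education, duration, H&Y) equals the
#' requested target. `alps_mean` is derived as `(alps_l + alps_r) / 2`.
#'
#' @param reference `"alps"` or `"coupling"` (selects the summary table and
#'   which markers exist).
#' @param n_multiplier integer scaling of every group size.
#' @param group_sizes optional named vector overriding the group sizes
#'   (names `pd_a`, `pd_na`, `hc`, each >= 2).
#' @param variables optional override of the per-variable parameters (same
#'   structure as `cohort_summaries()$variables`).
#' @param alps_l_hama_r,alps_r_hama_r,coupling_hama_r target partial
#'   correlations between each marker and HAMA over the PD groups
#'   (|r| < 1); the coupling target is used only for the "coupling"
#'   reference. Defaults are the reported cohort values.
#' @param lr_cor target within-group correlation between left and right
#'   ALPS (a subject-level trait; the printed SDs of the mean index imply
#'   roughly 0.8).
#' @param assign_by_hama if `TRUE`, PD group labels are reassigned by the
#'   HAMA >= 14 rule after simulation.
#' @param seed RNG seed.
#' @return `cohort_spec` object.
#' @export
cohort_spec <- function(reference = c("alps", "coupling"), n_multiplier = 1,
                        group_sizes = NULL, variables = NULL,
                        alps_l_hama_r = -0.244, alps_r_hama_r = -0.280,
                        coupling_hama_r = -0.317, lr_cor = 0.8,
                        assign_by_hama = FALSE, seed = NULL) {
  reference <- match.arg(reference)
  ref <- cohort_summaries(reference)
  if (!is.null(variables)) ref$variables <- variables
  if (is.null(group_sizes))
    group_sizes <- unlist(ref$groups) * n_multiplier
  group_sizes <- group_sizes[c("pd_a", "pd_na", "hc")]
  if (any(is.na(group_sizes)) || any(group_sizes < 2))
    stop("group sizes must be named pd_a/pd_na/hc and >= 2")
  for (v in names(ref$variables))
    for (g in names(ref$variables[[v]]))
      if (ref$variables[[v]][[g]][2] <= 0)
        stop(sprintf("sd of %s in group %s must be > 0", v, g))
  targets <- c(alps_l = alps_l_hama_r, alps_r = alps_r_hama_r)
  if (reference == "coupling") targets <- c(targets, coupling = coupling_hama_r)
  if (any(abs(targets) >= 1)) stop("target correlations must satisfy |r| < 1")
  if (abs(lr_cor) >= 1) stop("|lr_cor| must be < 1")
  structure(list(reference = reference, ref = ref,
                 group_sizes = group_sizes, targets = targets,
                 lr_cor = lr_cor, assign_by_hama = assign_by_hama,
                 seed = seed),
            class = "cohort_spec")
}

# Per-group (mean, sd) of a covariate for the mixture-moment computation;
# sex is Bernoulli(p_male).
cov_moments <- function(ref, var, groups) {
  if (var == "sex") {
    t(vapply(groups, function(g) {
      mf <- ref$sex_mf[[g]]
      p <- mf[1] / sum(mf)
      c(mean = p, sd = sqrt(p * (1 - p)))
    }, numeric(2)))
  } else {
    t(vapply(groups, function(g) {
      ms <- ref$variables[[var]][[g]]
      c(mean = ms[1], sd = ms[2])
    }, numeric(2)))
  }
}

# Closed-form calibration of the within-group marker-HAMA loading rho_w so
# that the population partial correlation of (marker, hama) given the
# covariates, over the PD two-group mixture, equals target_r. Within a
# group all variables are independent except the marker-hama pair, so every
# needed mixture moment is available analytically:
#   Cov(a,b) = sum_g w_g covW_g(a,b) + sum_g w_g (mu_ag - mu_a)(mu_bg - mu_b)
calibrate_marker_loading <- function(ref, marker, target_r,
                                     covars = c("age", "sex", "education",
                                                "duration", "hy"),
                                     groups = c("pd_a", "pd_na")) {
  n <- unlist(ref$groups[groups])
  w <- n / sum(n)
  btw <- function(ma, mb) sum(w * (ma - sum(w * ma)) * (mb - sum(w * mb)))

  H <- cov_moments(ref, "hama", groups)
  M <- cov_moments(ref, marker, groups)
  Cm <- lapply(covars, function(v) cov_moments(ref, v, groups))

  k <- length(covars)
  Vcc <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    Vcc[i, j] <- btw(Cm[[i]][, "mean"], Cm[[j]][, "mean"]) +
      if (i == j) sum(w * Cm[[i]][, "sd"]^2) else 0
  qH <- vapply(Cm, function(cm) btw(cm[, "mean"], H[, "mean"]), numeric(1))
  qM <- vapply(Cm, function(cm) btw(cm[, "mean"], M[, "mean"]), numeric(1))
  Vi <- solve(Vcc)

  var_h <- sum(w * H[, "sd"]^2) + btw(H[, "mean"], H[, "mean"])
  var_m <- sum(w * M[, "sd"]^2) + btw(M[, "mean"], M[, "mean"])
  var_h_res <- var_h - drop(t(qH) %*% Vi %*% qH)
  var_m_res <- var_m - drop(t(qM) %*% Vi %*% qM)
  s_mh <- btw(M[, "mean"], H[, "mean"])        # between-group covariance
  amp <- sum(w * M[, "sd"] * H[, "sd"])        # within coupling amplitude

  rho_w <- (target_r * sqrt(var_h_res * var_m_res) - s_mh +
              drop(t(qM) %*% Vi %*% qH)) / amp
  if (!is.finite(rho_w) || abs(rho_w) >= 0.999)
    stop(sprintf(
      "infeasible correlation target %g for %s: implied within-group loading %.3f",
      target_r, marker, rho_w))
  rho_w
}

#' Generate a synthetic cohort table
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with one row per subject: `subject_id`, `group`
#'   (factor pd_a/pd_na/hc), `sex` (1 = male, 0 = female), the clinical
#'   variables, and the glymphatic markers (`alps_l`, `alps_r`,
#'   `alps_mean`, plus `coupling` for the "coupling" reference). Variables
#'   not assessed in a group (e.g. disease duration for controls) are `NA`.
#'   The generator spec (including calibrated loadings) is attached as
#'   attribute `"spec"`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ref <- spec$ref
  markers <- names(spec$targets)
  rho_w <- vapply(markers, function(m)
    calibrate_marker_loading(ref, m, spec$targets[[m]]), numeric(1))

  # residual correlation between the left/right ALPS noise terms so that
  # the total within-group L-R correlation equals lr_cor
  rho_e <- (spec$lr_cor - rho_w["alps_l"] * rho_w["alps_r"]) /
    sqrt((1 - rho_w["alps_l"]^2) * (1 - rho_w["alps_r"]^2))
  if (!is.finite(rho_e) || abs(rho_e) > 1)
    stop("infeasible combination of lr_cor and marker-HAMA targets")

  plain_vars <- setdiff(names(ref$variables),
                        c("hama", "alps_l", "alps_r", "alps_mean", "coupling"))
  with_seed(spec$seed, {
    rows <- lapply(c("pd_a", "pd_na", "hc"), function(g) {
      n <- spec$group_sizes[[g]]
      out <- data.frame(group = rep(g, n))
      mf <- ref$sex_mf[[g]]
      out$sex <- rbinom(n, 1, mf[1] / sum(mf))
      for (v in plain_vars) {
        ms <- ref$variables[[v]][[g]]
        out[[v]] <- if (is.null(ms)) NA_real_ else rnorm(n, ms[1], ms[2])
      }
      hm <- ref$variables$hama[[g]]
      z_h <- rnorm(n)
      out$hama <- hm[1] + hm[2] * z_h
      e_l <- rnorm(n)
      e_r <- rho_e * e_l + sqrt(1 - rho_e^2) * rnorm(n)
      noise <- list(alps_l = e_l, alps_r = e_r, coupling = rnorm(n))
      for (m in markers) {
        ms <- ref$variables[[m]][[g]]
        out[[m]] <- ms[1] + ms[2] * (rho_w[[m]] * z_h +
                                       sqrt(1 - rho_w[[m]]^2) * noise[[m]])
      }
      out
    })
    df <- do.call(rbind, rows)
    df$alps_mean <- (df$alps_l + df$alps_r) / 2
    df <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(df))), df)
    if (spec$assign_by_hama) {
      pd <- df$group != "hc"
      df$group[pd] <- ifelse(df$hama[pd] >= 14, "pd_a", "pd_na")
    }
    df$group <- factor(df$group, levels = c("pd_a", "pd_na", "hc"))
    attr(df, "spec") <- c(spec, list(rho_w = rho_w, rho_e = rho_e))
    df
  })
}
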