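#' Specify a coupled gBOLD/CSF series pair
#'
#' Minimal delay-and-scale coupling model: a smoothed white-noise gBOLD
#' series, and a CSF series equal to a `lag`-sample delayed copy of it,
#' scaled so that `amplitude` is the population correlation magnitude,
#' with optional further additive white noise. No hemodynamic model is
#' implied; the construction reproduces a lagged (anti-)correlation with a
#' known analytic value.
#'
#' @param n_timepoints series length (default 300 volumes).
#' @param tr sampling interval, s (default 1.5).
#' @param lag delay of the CSF series behind gBOLD, in samples (default 3).
#' @param amplitude coupling magnitude in correlation units, `[0, 1]`.
#' @param sign +1 or -1 (default -1: CSF anti-correlated with lagged gBOLD).
#' @param smooth_fwhm temporal Gaussian smoothing FWHM applied to the gBOLD
#'   process, s.
#' @param noise_sd additional white noise on the CSF series, in units of the
#'   clean CSF standard deviation; the expected correlation at the coupling
#'   lag is `sign * amplitude / sqrt(1 + noise_sd^2)`.
#' @param seed RNG seed.
#' @return `coupled_series_spec` object.
#' @export
coupled_series_spec <- function(n_timepoints = 300, tr = 1.5, lag = 3,
                                amplitude = 0.35, sign = -1, smooth_fwhm = 6,
                                noise_sd = 0, seed = NULL) {
  stopifnot_scalar(tr, "tr", positive = TRUE)
  if (abs(amplitude) > 1) stop("|amplitude| must be <= 1")
  if (!sign %in% c(-1, 1)) stop("sign must be +1 or -1")
  if (lag < 0) stop("lag must be >= 0 samples")
  if (lag >= n_timepoints) stop("lag must be smaller than the series length")
  if (n_timepoints <= 10 + 2 * max(lag, 5))
    stop("series too short: need n_timepoints > 10 + 2 * max lag")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_timepoints = as.integer(n_timepoints), tr = tr,
                 lag = as.integer(lag), amplitude = amplitude, sign = sign,
                 smooth_fwhm = smooth_fwhm, noise_sd = noise_sd, seed = seed),
            class = "coupled_series_spec")
}

# Gaussian smoothing with edge renormalisation (kernel truncated at 4 sd)
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  h <- max(1L, ceiling(4 * sd_samples))
  k <- exp(-((-h:h)^2) / (2 * sd_samples^2))
  n <- length(x)
  num <- stats::convolve(c(rep(0, h), x, rep(0, h)), k, type = "filter")
  den <- stats::convolve(c(rep(0, h), rep(1, n), rep(0, h)), k, type = "filter")
  num / den
}

#' Generate a coupled gBOLD/CSF signal pair
#'
#' @param spec a [coupled_series_spec()].
#' @return `signal_pair`: list with standardized `gbold` and `csf` series
#'   (zero mean, unit variance), `tr`, and `spec`. The attribute
#'   `expected_r` records the analytic correlation at the coupling lag,
#'   `sign * amplitude / sqrt(1 + noise_sd^2)`.
#' @export
generate_coupled_series <- function(spec) {
  stopifnot(inherits(spec, "coupled_series_spec"))
  n <- spec$n_timepoints
  lag <- spec$lag
  with_seed(spec$seed, {
    base <- gaussian_smooth(rnorm(n + lag), spec$smooth_fwhm / 2.35482 / spec$tr)
    gbold <- standardize(base[(lag + 1):(lag + n)])
    lagged <- standardize(base[1:n])          # = gbold delayed by `lag`
    eta <- standardize(rnorm(n))
    a <- spec$amplitude
    csf_clean <- spec$sign * (a * lagged + sqrt(1 - a^2) * eta)
    csf <- standardize(csf_clean + spec$noise_sd * rnorm(n))
    signal_pair(gbold, csf, spec$tr, spec = spec)
  })
}

#' Construct a signal pair
#'
#' @param gbold,csf equal-length numeric series; standardized to zero mean
#'   and unit variance on construction.
#' @param tr sampling interval, s.
#' @param spec optional generator spec to carry along.
#' @return `signal_pair` object.
#' @export
signal_pair <- function(gbold, csf, tr, spec = NULL) {
  if (length(gbold) != length(csf)) stop("gbold and csf must have equal length")
  stopifnot_scalar(tr, "tr", positive = TRUE)
  out <- structure(list(gbold = standardize(gbold), csf = standardize(csf),
                        tr = tr, spec = spec),
                   class = "signal_pair")
  if (!is.null(spec))
    attr(out, "expected_r") <-
      spec$sign * spec$amplitude / sqrt(1 + spec$noise_sd^2)
  out
}
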