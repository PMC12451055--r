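#' Mean signal over a mask
#'
#' @param data 4D array (x, y, z, t).
#' @param mask logical or 0/1 3D array on the same grid; must be non-empty.
#' @return numeric vector: per-timepoint mean over mask voxels.
#' @export
extract_mean_signal <- function(data, mask) {
  d4 <- dim(data)
  if (length(d4) != 4L) stop("data must be a 4D array (x, y, z, t)")
  if (!identical(as.integer(dim(mask)), as.integer(d4[1:3])))
    stop("mask grid does not match the data")
  idx <- which(as.logical(mask))
  if (length(idx) == 0L) stop("empty mask")
  m <- matrix(data, prod(d4[1:3]), d4[4])[idx, , drop = FALSE]
  colMeans(m)
}

#' Preprocess a BOLD or CSF time series
#'
#' Drops initial volumes (magnetisation stabilisation), removes the
#' least-squares linear trend, applies a zero-phase (forward-backward)
#' Butterworth band-pass, and standardizes to zero mean / unit variance.
#' Zero phase matters because the downstream statistic is a lag. A series
#' that is constant after filtering (e.g. a pure ramp) is returned as zeros
#' rather than standardized.
#'
#' @param x raw time series.
#' @param tr sampling interval, s.
#' @param band length-2 pass band in Hz (default 0.01-0.1).
#' @param drop number of initial points to remove (default 10).
#' @param order Butterworth order (default 4).
#' @param standardize if `FALSE`, return the detrended band-passed series
#'   without the final scaling (useful for probing the filter gain).
#' @return filtered, standardized series of length `length(x) - drop`.
#' @export
preprocess_signal <- function(x, tr, band = c(0.01, 0.1), drop = 10,
                              order = 4, standardize = TRUE) {
  stopifnot_scalar(tr, "tr", positive = TRUE)
  nyq <- 1 / (2 * tr)
  if (length(band) != 2L || band[1] <= 0 || band[1] >= band[2])
    stop("band must be 0 < low < high")
  if (band[2] >= nyq)
    stop(sprintf("band high edge %.4g Hz is at/above Nyquist %.4g Hz",
                 band[2], nyq))
  if (drop < 0 || drop >= length(x)) stop("invalid drop count")
  y <- x[(drop + 1):length(x)]
  n <- length(y)
  if (n < 30) stop("series too short after dropping initial points")
  if (n * tr < 4 / band[1])
    warning("series shorter than four cycles of the low band edge")
  t0 <- seq_len(n)
  y <- y - (lm.fit(cbind(1, t0), y)$fitted.values)
  bf <- signal::butter(order, band / nyq, type = "pass")
  y <- signal::filtfilt(bf, y)
  if (!standardize) return(y)
  s <- sd(y)
  if (!is.finite(s) || s < 1e-12 * max(sd(x), 1e-300)) {
    warning("series is constant after filtering; returning zeros")
    return(rep(0, n))
  }
  (y - mean(y)) / s
}
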