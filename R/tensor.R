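#' Construct a tensor volume
#'
#' Container for per-voxel axis diffusivities and fractional anisotropy on
#' one grid. If `fa` is missing it is computed from the tensor components
#' (off-diagonals default to zero).
#'
#' @param dxx,dyy,dzz 3D arrays of diffusivities along x (left-right),
#'   y (anterior-posterior), z (inferior-superior), mm^2/s.
#' @param dxy,dxz,dyz optional off-diagonal arrays (default zero).
#' @param fa optional fractional anisotropy array in `[0, 1]`.
#' @param voxel_size voxel edge length, mm.
#' @param qc optional list of fit diagnostics.
#' @return `tensor_volume` object.
#' @export
tensor_volume <- function(dxx, dyy, dzz, dxy = NULL, dxz = NULL, dyz = NULL,
                          fa = NULL, voxel_size = 1, qc = NULL) {
  d <- dim(dxx)
  if (!identical(dim(dyy), d) || !identical(dim(dzz), d))
    stop("diffusivity maps must share one grid")
  if (is.null(fa)) {
    z <- array(0, d)
    fa <- fa_map(dxx, dyy, dzz,
                 if (is.null(dxy)) z else dxy,
                 if (is.null(dxz)) z else dxz,
                 if (is.null(dyz)) z else dyz)
  }
  structure(list(dxx = dxx, dyy = dyy, dzz = dzz,
                 dxy = dxy, dxz = dxz, dyz = dyz, fa = fa,
                 grid_shape = as.integer(d), voxel_size = voxel_size,
                 qc = qc),
            class = "tensor_volume")
}

# FA from tensor components without eigendecomposition:
# FA^2 = (3/2) * ||D - (tr/3) I||_F^2 / ||D||_F^2, identical to the
# eigenvalue formula for symmetric D. Clamped to [0, 1] (noisy fits can
# produce negative eigenvalues).
fa_map <- function(dxx, dyy, dzz, dxy, dxz, dyz) {
  norm2 <- dxx^2 + dyy^2 + dzz^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  tr <- dxx + dyy + dzz
  dev2 <- norm2 - tr^2 / 3
  fa <- sqrt(1.5 * pmax(dev2, 0) / norm2)
  fa[norm2 <= 0] <- 0
  pmin(pmax(fa, 0), 1)
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per-voxel ordinary (unweighted) least squares on ln(S) against the
#' standard 7-column tensor design (intercept = ln S0 plus the six unique
#' tensor elements). Voxels containing any non-positive signal are excluded
#' from the fit (the log is undefined), set to `NA`, and reported in the QC
#' slot rather than clamped.
#'
#' @param dwi 4D array (x, y, z, volume).
#' @param bvals numeric vector of per-volume b-values, s/mm^2; at least one
#'   volume with b <= `b0_threshold` is required.
#' @param bvecs 3 x nvol matrix of gradient directions; non-zero-b columns
#'   must be unit-norm.
#' @param mask optional logical 3D array restricting the fit.
#' @param voxel_size voxel edge length, mm.
#' @param b0_threshold b-values at or below this count as b=0.
#' @return [tensor_volume()] with `dxx`, `dyy`, `dzz`, off-diagonals, `fa`,
#'   and `qc` (list: `n_fit`, `n_excluded`, `excluded` linear indices,
#'   `s0` array).
#' @export
fit_diffusion_tensor <- function(dwi, bvals, bvecs, mask = NULL,
                                 voxel_size = 1, b0_threshold = 10) {
  d4 <- dim(dwi)
  if (length(d4) != 4L) stop("dwi must be a 4D array (x, y, z, volume)")
  d <- d4[1:3]
  nvol <- d4[4]
  if (length(bvals) != nvol || ncol(bvecs) != nvol)
    stop("bvals/bvecs do not match the number of volumes")
  is_b0 <- bvals <= b0_threshold
  if (!any(is_b0)) stop("need at least one b=0 volume")
  nrm <- sqrt(colSums(bvecs^2))
  if (any(abs(nrm[!is_b0] - 1) > 1e-6))
    stop("non-zero-b gradient directions must be unit-norm")
  # distinct directions up to sign (g and -g give the same design row)
  key <- apply(round(sweep(bvecs[, !is_b0, drop = FALSE], 2,
                           sign(bvecs[3, !is_b0] + 1e-12), `*`), 6), 2,
               paste, collapse = ",")
  if (length(unique(key)) < 6)
    stop("tensor fit is under-determined: need >= 6 distinct directions")

  gx <- bvecs[1, ]; gy <- bvecs[2, ]; gz <- bvecs[3, ]
  X <- cbind(1, -bvals * gx^2, -bvals * gy^2, -bvals * gz^2,
             -2 * bvals * gx * gy, -2 * bvals * gx * gz, -2 * bvals * gy * gz)
  if (qr(X)$rank < 7)
    stop("tensor fit is under-determined: design rank < 7")
  proj <- solve(crossprod(X), t(X))                 # 7 x nvol

  V <- prod(d)
  vox <- if (is.null(mask)) seq_len(V) else {
    if (!identical(dim(mask), as.integer(d)) && !identical(dim(mask), d))
      stop("mask grid does not match dwi")
    which(as.logical(mask))
  }
  if (length(vox) == 0L) stop("empty fit mask")

  S <- matrix(dwi, V, nvol)[vox, , drop = FALSE]    # voxels x volumes
  ok <- rowSums(S <= 0) == 0L
  beta <- matrix(NA_real_, 7, length(vox))
  if (any(ok)) beta[, ok] <- proj %*% t(log(S[ok, , drop = FALSE]))

  put <- function(row) {
    a <- array(NA_real_, d)
    a[vox] <- beta[row, ]
    a
  }
  dxx <- put(2); dyy <- put(3); dzz <- put(4)
  dxy <- put(5); dxz <- put(6); dyz <- put(7)
  s0 <- array(NA_real_, d); s0[vox] <- exp(beta[1, ])
  qc <- list(n_fit = sum(ok), n_excluded = sum(!ok),
             excluded = vox[!ok], s0 = s0)
  tensor_volume(dxx, dyy, dzz, dxy, dxz, dyz,
                voxel_size = voxel_size, qc = qc)
}
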