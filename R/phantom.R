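#' Quasi-uniform unit gradient directions
#'
#' Deterministic Fibonacci-sphere scheme; adequate for simulation since the
#' tensor design only needs well-spread, non-coplanar unit vectors.
#'
#' @param n number of directions (>= 6).
#' @return 3 x n matrix of unit column vectors.
#' @export
fibonacci_directions <- function(n) {
  if (n < 6) stop("a diffusion tensor has 6 free elements; need >= 6 directions")
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Default ALPS region-of-interest set
#'
#' Sphere centres for the left/right superior corona radiata (SCR,
#' projection fibres) and superior longitudinal fasciculus (SLF,
#' association fibres), given as 0-based voxel indices on the 1 mm
#' 182 x 218 x 182 FA template grid. On coarser grids the centres are
#' divided by the voxel size and rounded (half to even).
#'
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_size voxel edge length in mm (scalar, isotropic).
#' @param diameter_mm ROI sphere diameter in mm.
#' @return An object of class `alps_rois`: list with `centers` (4 x 3
#'   matrix, rows l_scr, r_scr, l_slf, r_slf, 0-based voxel indices),
#'   `diameter_mm`, `grid_shape`, `voxel_size`.
#' @export
default_alps_rois <- function(grid_shape = c(182L, 218L, 182L), voxel_size = 1,
                              diameter_mm = 5) {
  centers_1mm <- rbind(
    l_scr = c(116, 110, 99),
    r_scr = c(64, 110, 99),
    l_slf = c(128, 110, 99),
    r_slf = c(51, 110, 99))
  alps_rois(round(centers_1mm / voxel_size), grid_shape, voxel_size, diameter_mm)
}

#' Construct an ALPS ROI set
#'
#' @param centers 4 x 3 matrix of 0-based voxel indices with rows named
#'   `l_scr`, `r_scr`, `l_slf`, `r_slf`.
#' @inheritParams default_alps_rois
#' @return `alps_rois` object.
#' @export
alps_rois <- function(centers, grid_shape, voxel_size = 1, diameter_mm = 5) {
  centers <- as.matrix(centers)
  need <- c("l_scr", "r_scr", "l_slf", "r_slf")
  if (!all(need %in% rownames(centers)))
    stop("centers must have rows l_scr, r_scr, l_slf, r_slf")
  centers <- centers[need, , drop = FALSE]
  if (any(centers < 0) || any(sweep(centers, 2, grid_shape, ">=")))
    stop("ROI centre outside the grid")
  structure(list(centers = centers, diameter_mm = diameter_mm,
                 grid_shape = as.integer(grid_shape), voxel_size = voxel_size),
            class = "alps_rois")
}

#' Default phantom region definitions
#'
#' Axis-aligned boxes around the four ALPS ROI centres. SCR boxes carry a
#' projection-fibre tensor (principal axis z, inferior-superior); SLF boxes
#' an association-fibre tensor (principal axis y, anterior-posterior).
#' Default eigenvalues give a ground-truth ALPS index of
#' (1.00 + 0.82) / (0.68 + 0.68) = 1.3382 in both hemispheres, in the range
#' reported for healthy adults.
#'
#' @inheritParams default_alps_rois
#' @param halfwidth_mm half edge length of each box, mm.
#' @param proj_tensor,assoc_tensor length-3 diagonal tensor eigenvalues
#'   (Dxx, Dyy, Dzz) in mm^2/s.
#' @return named list of region definitions (`type`, `center`,
#'   `halfwidth_mm`, `tensor`).
#' @export
default_phantom_regions <- function(grid_shape = c(91L, 109L, 91L),
                                    voxel_size = 2, halfwidth_mm = 5,
                                    proj_tensor = c(1.00, 0.68, 1.45) * 1e-3,
                                    assoc_tensor = c(0.82, 1.35, 0.68) * 1e-3) {
  rois <- default_alps_rois(grid_shape, voxel_size)
  mk <- function(name, tensor)
    list(type = "box", center = rois$centers[name, ],
         halfwidth_mm = halfwidth_mm, tensor = tensor)
  list(l_scr = mk("l_scr", proj_tensor), r_scr = mk("r_scr", proj_tensor),
       l_slf = mk("l_slf", assoc_tensor), r_slf = mk("r_slf", assoc_tensor))
}

#' Specify a DWI phantom
#'
#' Piecewise-constant diagonal-tensor phantom: labelled regions embedded in
#' an isotropic background, sampled with one (or more) b=0 volume plus
#' `n_directions` diffusion-weighted volumes following the mono-exponential
#' tensor model S = S0 exp(-b g' D g).
#'
#' @param grid_shape length-3 voxel grid (default: 2 mm template grid).
#' @param voxel_size voxel edge length, mm.
#' @param regions named list of region definitions as produced by
#'   [default_phantom_regions()]; each has `type` ("box" or "sphere"),
#'   `center` (0-based voxel triplet), `halfwidth_mm` (box) or
#'   `diameter_mm` (sphere), and `tensor` (diagonal eigenvalues, mm^2/s).
#' @param background_adc isotropic background diffusivity, mm^2/s.
#' @param b_value diffusion weighting, s/mm^2.
#' @param n_directions number of non-zero gradient directions (>= 6).
#' @param n_b0 number of b=0 volumes.
#' @param s0 non-diffusion-weighted signal level.
#' @param noise_sd noise standard deviation on the signal scale
#'   (SNR = s0 / noise_sd).
#' @param noise_model "gaussian" (additive) or "rician" (magnitude of a
#'   complex signal with Gaussian noise on both channels).
#' @param seed RNG seed recorded in the output metadata.
#' @return `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(91L, 109L, 91L), voxel_size = 2,
                         regions = default_phantom_regions(grid_shape, voxel_size),
                         background_adc = 0.7e-3, b_value = 1000,
                         n_directions = 64, n_b0 = 1, s0 = 1,
                         noise_sd = 0, noise_model = c("gaussian", "rician"),
                         seed = NULL) {
  noise_model <- match.arg(noise_model)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("grid_shape must be three positive integers")
  stopifnot_scalar(voxel_size, "voxel_size", positive = TRUE)
  stopifnot_scalar(background_adc, "background_adc", positive = TRUE)
  stopifnot_scalar(b_value, "b_value", positive = TRUE)
  stopifnot_scalar(s0, "s0", positive = TRUE)
  if (n_directions < 6)
    stop("a diffusion tensor has 6 free elements; need n_directions >= 6")
  if (n_b0 < 1) stop("need at least one b=0 volume")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(regions) > 0 &&
      (is.null(names(regions)) || any(!nzchar(names(regions)))))
    stop("regions must be a named list")
  for (nm in names(regions)) {
    rg <- regions[[nm]]
    if (any(rg$tensor <= 0) || length(rg$tensor) != 3L)
      stop(sprintf("region '%s': tensor must be 3 positive diffusivities", nm))
    idx <- region_voxels(rg, grid_shape, voxel_size, clip = FALSE)
    if (is.null(idx))
      stop(sprintf("region '%s' extends outside the grid", nm))
  }
  structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                 regions = regions, background_adc = background_adc,
                 b_value = b_value, n_directions = as.integer(n_directions),
                 n_b0 = as.integer(n_b0), s0 = s0, noise_sd = noise_sd,
                 noise_model = noise_model, seed = seed),
            class = "phantom_spec")
}

# linear voxel indices (1-based) of a region; clip=FALSE returns NULL if the
# region is not fully inside the grid
region_voxels <- function(rg, grid_shape, voxel_size, clip = TRUE) {
  if (rg$type == "box") {
    hw <- round(rg$halfwidth_mm / voxel_size)
    lo <- rg$center - hw
    hi <- rg$center + hw
    if (!clip && (any(lo < 0) || any(hi > grid_shape - 1L))) return(NULL)
    lo <- pmax(lo, 0)
    hi <- pmin(hi, grid_shape - 1L)
    g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
    1L + g$x + grid_shape[1] * (g$y + grid_shape[2] * g$z)
  } else if (rg$type == "sphere") {
    r_vox <- (rg$diameter_mm / 2) / voxel_size
    if (!clip && (any(rg$center - ceiling(r_vox) < 0) ||
                  any(rg$center + ceiling(r_vox) > grid_shape - 1L)))
      return(NULL)
    m <- make_sphere_mask(rg$center, rg$diameter_mm, grid_shape, voxel_size)
    which(m)
  } else stop("unknown region type: ", rg$type)
}

#' Generate a DWI phantom with known ground truth
#'
#' Noise-free signal in every voxel follows S = S0 exp(-b g' D g) for the
#' voxel's (diagonal) tensor; noise is then added per `spec$noise_model`.
#' The ground-truth tensor maps are returned alongside the data.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `dwi_phantom`: `dwi` (4D array x,y,z,volume),
#'   `bvals` (per-volume b-values), `bvecs` (3 x nvol unit directions),
#'   `truth` (ground-truth [tensor_volume]), `labels` (integer 3D region
#'   label array, 0 = background), `region_names`, and `spec`.
#' @export
generate_dwi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  V <- prod(d)
  nvol <- spec$n_b0 + spec$n_directions
  bvals <- c(rep(0, spec$n_b0), rep(spec$b_value, spec$n_directions))
  bvecs <- cbind(matrix(0, 3, spec$n_b0), fibonacci_directions(spec$n_directions))

  labels <- integer(V)
  region_names <- names(spec$regions)
  tensors <- rbind(rep(spec$background_adc, 3),
                   t(vapply(spec$regions, `[[`, numeric(3), "tensor")))
  for (k in seq_along(spec$regions))
    labels[region_voxels(spec$regions[[k]], d, spec$voxel_size)] <- k

  # noise-free signal per label per volume: S0 * exp(-b * (gx^2 Dxx + ...))
  g2 <- bvecs^2                                    # 3 x nvol
  bq <- tensors %*% g2                             # (K+1) x nvol, g'Dg
  region_signal <- spec$s0 * exp(-sweep(bq, 2, bvals, `*`))

  model <- if (spec$noise_sd <= 0) 0L else
    switch(spec$noise_model, gaussian = 1L, rician = 2L)
  dwi <- with_seed(spec$seed,
                   .phantom_signal(labels, region_signal, spec$noise_sd, model))
  dim(dwi) <- c(d, nvol)

  lab1 <- labels + 1L
  truth <- tensor_volume(
    dxx = array(tensors[lab1, 1], d),
    dyy = array(tensors[lab1, 2], d),
    dzz = array(tensors[lab1, 3], d),
    voxel_size = spec$voxel_size)
  dim(labels) <- d
  structure(list(dwi = dwi, bvals = bvals, bvecs = bvecs, truth = truth,
                 labels = labels, region_names = region_names, spec = spec),
            class = "dwi_phantom")
}

#' Ground-truth ALPS indices implied by a phantom specification
#'
#' Hand-computable oracle: the ALPS ratio of the prescribed regional
#' diffusivities, independent of the image pipeline.
#'
#' @param spec a [phantom_spec()] whose regions include `l_scr`, `r_scr`,
#'   `l_slf`, `r_slf`.
#' @return list with `alps_left`, `alps_right`, `alps_mean`.
#' @export
phantom_truth_alps <- function(spec) {
  tn <- function(nm) spec$regions[[nm]]$tensor
  left <- mean(c(tn("l_scr")[1], tn("l_slf")[1])) /
    mean(c(tn("l_scr")[2], tn("l_slf")[3]))
  right <- mean(c(tn("r_scr")[1], tn("r_slf")[1])) /
    mean(c(tn("r_scr")[2], tn("r_slf")[3]))
  list(alps_left = left, alps_right = right, alps_mean = (left + right) / 2)
}
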