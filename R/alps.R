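#' Spherical voxel mask
#'
#' Marks voxels whose centre lies within `diameter_mm / 2` (inclusive) of
#' the centre voxel's centre. Deterministic and grid-resolution independent;
#' a sphere clipped by the grid boundary is truncated with a warning.
#'
#' @param center 0-based voxel index triplet.
#' @param diameter_mm sphere diameter, mm (0 gives the single centre voxel).
#' @param grid_shape length-3 voxel grid.
#' @param voxel_size voxel edge length in mm (scalar or length-3).
#' @return logical 3D array.
#' @export
make_sphere_mask <- function(center, diameter_mm, grid_shape, voxel_size = 1) {
  grid_shape <- as.integer(grid_shape)
  vs <- rep_len(voxel_size, 3L)
  if (length(center) != 3L || any(center < 0) || any(center > grid_shape - 1L))
    stop("sphere centre outside the grid")
  r <- diameter_mm / 2
  kmax <- floor(r / vs)
  off <- expand.grid(x = -kmax[1]:kmax[1], y = -kmax[2]:kmax[2],
                     z = -kmax[3]:kmax[3])
  keep <- (off$x * vs[1])^2 + (off$y * vs[2])^2 + (off$z * vs[3])^2 <=
    r^2 + 1e-9
  co <- cbind(center[1] + off$x[keep], center[2] + off$y[keep],
              center[3] + off$z[keep])
  inside <- co[, 1] >= 0 & co[, 1] < grid_shape[1] &
    co[, 2] >= 0 & co[, 2] < grid_shape[2] &
    co[, 3] >= 0 & co[, 3] < grid_shape[3]
  if (!all(inside)) {
    warning("sphere clipped by the grid boundary; proceeding with the truncated sphere")
    co <- co[inside, , drop = FALSE]
  }
  m <- array(FALSE, grid_shape)
  m[1L + co[, 1] + grid_shape[1] * (co[, 2] + grid_shape[2] * co[, 3])] <- TRUE
  m
}

#' Compute DTI-ALPS indices
#'
#' Per hemisphere, ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj,
#' Dzz_assoc), where each term is the mean diffusivity over a 5 mm spherical
#' ROI: Dxx in the projection-fibre (SCR) and association-fibre (SLF)
#' regions over the diffusivities parallel to each tract (Dyy in SCR, Dzz in
#' SLF). The mean index averages the two hemispheric ratios. The index is a
#' dimensionless ratio.
#'
#' @param tv a [tensor_volume()].
#' @param rois an [alps_rois()] set; defaults to the template coordinates
#'   scaled to the volume's grid.
#' @return `alps_result`: list with `alps_left`, `alps_right`, `alps_mean`
#'   and `roi_means` (the eight ROI mean diffusivities, mm^2/s).
#' @export
compute_alps_index <- function(tv, rois = NULL) {
  stopifnot(inherits(tv, "tensor_volume"))
  if (is.null(rois))
    rois <- default_alps_rois(tv$grid_shape, tv$voxel_size)
  stopifnot(inherits(rois, "alps_rois"))
  if (!identical(as.integer(rois$grid_shape), as.integer(tv$grid_shape)))
    stop("ROI set and tensor volume are on different grids")

  roi_mean <- function(map, roi) {
    m <- make_sphere_mask(rois$centers[roi, ], rois$diameter_mm,
                          tv$grid_shape, tv$voxel_size)
    v <- map[m]
    if (all(is.na(v)))
      stop(sprintf("ROI '%s' contains no fitted voxels", roi))
    mean(v, na.rm = TRUE)
  }
  rm <- c(
    dxx_proj_l = roi_mean(tv$dxx, "l_scr"),
    dxx_assoc_l = roi_mean(tv$dxx, "l_slf"),
    dyy_proj_l = roi_mean(tv$dyy, "l_scr"),
    dzz_assoc_l = roi_mean(tv$dzz, "l_slf"),
    dxx_proj_r = roi_mean(tv$dxx, "r_scr"),
    dxx_assoc_r = roi_mean(tv$dxx, "r_slf"),
    dyy_proj_r = roi_mean(tv$dyy, "r_scr"),
    dzz_assoc_r = roi_mean(tv$dzz, "r_slf"))

  den_l <- mean(rm[c("dyy_proj_l", "dzz_assoc_l")])
  den_r <- mean(rm[c("dyy_proj_r", "dzz_assoc_r")])
  if (den_l == 0 || den_r == 0)
    stop("zero denominator in the ALPS ratio; ROI means: ",
         paste(names(rm), signif(rm, 4), sep = "=", collapse = ", "))
  left <- mean(rm[c("dxx_proj_l", "dxx_assoc_l")]) / den_l
  right <- mean(rm[c("dxx_proj_r", "dxx_assoc_r")]) / den_r
  structure(list(alps_left = left, alps_right = right,
                 alps_mean = (left + right) / 2, roi_means = rm, rois = rois),
            class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("ALPS indices: left %.4f, right %.4f, mean %.4f\n",
              x$alps_left, x$alps_right, x$alps_mean))
  invisible(x)
}

#' One-row per-subject ALPS table
#'
#' @param result an `alps_result`.
#' @param subject_id identifier for the row.
#' @return data.frame with the three indices and the eight ROI means.
#' @export
alps_row <- function(result, subject_id = NA_character_) {
  stopifnot(inherits(result, "alps_result"))
  cbind(data.frame(subject_id = subject_id,
                   alps_left = result$alps_left,
                   alps_right = result$alps_right,
                   alps_mean = result$alps_mean),
        as.data.frame(as.list(result$roi_means)))
}
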