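test_that("sphere masks match brute-force voxel enumeration", {
  grid <- c(21L, 21L, 21L)
  # 5 mm diameter on a 1 mm grid: 81 voxels; on a 2 mm grid: 7 voxels
  for (vs in c(1, 2)) {
    m <- make_sphere_mask(c(10, 10, 10), 5, grid, vs)
    expect_equal(sum(m), oracle_sphere_count(5, vs))
  }
  expect_equal(sum(make_sphere_mask(c(10, 10, 10), 5, grid, 1)), 81L)
  expect_equal(sum(make_sphere_mask(c(10, 10, 10), 5, grid, 2)), 7L)
  # degenerate sphere: single voxel at the centre
  m0 <- make_sphere_mask(c(3, 4, 5), 0, grid, 1)
  expect_equal(sum(m0), 1L)
  expect_true(m0[4, 5, 6])
  # clipped sphere warns and proceeds truncated
  expect_warning(mc <- make_sphere_mask(c(0, 10, 10), 5, grid, 1), "clipped")
  expect_lt(sum(mc), 81L)
  expect_error(make_sphere_mask(c(-1, 10, 10), 5, grid, 1), "outside")
})

const_tv <- function(rois, dxx_proj, dxx_assoc, dyy, dzz) {
  grid <- rois$grid_shape
  dxx <- array(dxx_proj, grid)
  for (r in c("l_slf", "r_slf"))
    dxx[make_sphere_mask(rois$centers[r, ], rois$diameter_mm, grid,
                         rois$voxel_size)] <- dxx_assoc
  tensor_volume(dxx, array(dyy, grid), array(dzz, grid),
                voxel_size = rois$voxel_size)
}

test_that("ALPS index reproduces direct arithmetic on the ROI means", {
  rois <- small_phantom_setup()$rois
  # all four terms equal -> exactly 1
  tv1 <- const_tv(rois, 1e-3, 1e-3, 1e-3, 1e-3)
  r1 <- compute_alps_index(tv1, rois)
  expect_equal(r1$alps_left, 1, tolerance = 1e-12)
  expect_equal(r1$alps_right, 1, tolerance = 1e-12)
  # mean(1.0, 1.2) / mean(0.7, 0.9) = 1.375
  tv2 <- const_tv(rois, 1.0e-3, 1.2e-3, 0.7e-3, 0.9e-3)
  r2 <- compute_alps_index(tv2, rois)
  expect_equal(r2$alps_left, 1.375, tolerance = 1e-12)
  expect_equal(r2$alps_mean, 1.375, tolerance = 1e-12)
})

random_tv <- function(rois, seed) {
  grid <- rois$grid_shape
  with_seed(seed, tensor_volume(
    array(runif(prod(grid), 0.5e-3, 1.5e-3), grid),
    array(runif(prod(grid), 0.5e-3, 1.5e-3), grid),
    array(runif(prod(grid), 0.5e-3, 1.5e-3), grid),
    voxel_size = rois$voxel_size))
}

test_that("ALPS is scale-invariant and the mean index is the hemispheric average", {
  rois <- small_phantom_setup()$rois
  for (seed in 1:5) {
    tv <- random_tv(rois, seed)
    r <- compute_alps_index(tv, rois)
    expect_equal(r$alps_mean, (r$alps_left + r$alps_right) / 2,
                 tolerance = 1e-14)
    tv_scaled <- tensor_volume(tv$dxx * 3.7, tv$dyy * 3.7, tv$dzz * 3.7,
                               voxel_size = tv$voxel_size)
    rs <- compute_alps_index(tv_scaled, rois)
    expect_equal(rs$alps_left, r$alps_left, tolerance = 1e-12)
    expect_equal(rs$alps_right, r$alps_right, tolerance = 1e-12)
  }
})

test_that("mirroring the volume across the mid-sagittal plane swaps the hemispheric indices", {
  st <- small_phantom_setup()
  rois <- st$rois   # centres chosen mirror-symmetric: x -> 39 - x
  tv <- random_tv(rois, 7)
  mirror <- function(a) a[dim(a)[1]:1, , , drop = FALSE]
  tvm <- tensor_volume(mirror(tv$dxx), mirror(tv$dyy), mirror(tv$dzz),
                       voxel_size = tv$voxel_size)
  r <- compute_alps_index(tv, rois)
  rm <- compute_alps_index(tvm, rois)
  expect_equal(rm$alps_left, r$alps_right, tolerance = 1e-14)
  expect_equal(rm$alps_right, r$alps_left, tolerance = 1e-14)
  expect_equal(rm$alps_mean, r$alps_mean, tolerance = 1e-14)
})

test_that("noise-free phantom ALPS equals the hand-computed regional ratio", {
  st <- small_phantom_setup(proj_l = c(1.1, 0.5, 1.5) * 1e-3,
                            proj_r = c(0.9, 0.7, 1.4) * 1e-3,
                            assoc_l = c(0.8, 1.3, 0.6) * 1e-3,
                            assoc_r = c(0.85, 1.25, 0.7) * 1e-3)
  ph <- generate_dwi_phantom(st$spec)
  tv <- fit_diffusion_tensor(ph$dwi, ph$bvals, ph$bvecs,
                             mask = roi_union_mask(st$rois), voxel_size = 2)
  got <- compute_alps_index(tv, st$rois)
  truth <- phantom_truth_alps(st$spec)
  # oracle: arithmetic on the spec, e.g. left = mean(1.1, 0.8)/mean(0.5, 0.6)
  expect_equal(truth$alps_left, mean(c(1.1, 0.8)) / mean(c(0.5, 0.6)),
               tolerance = 1e-12)
  expect_equal(got$alps_left, truth$alps_left, tolerance = 1e-10)
  expect_equal(got$alps_right, truth$alps_right, tolerance = 1e-10)
  expect_equal(got$alps_mean, truth$alps_mean, tolerance = 1e-10)
})

test_that("default template ROI set uses the printed coordinates and stays on-grid", {
  rois <- default_alps_rois()
  expect_equal(unname(rois$centers["l_scr", ]), c(116, 110, 99))
  expect_equal(unname(rois$centers["r_slf", ]), c(51, 110, 99))
  # SCR and SLF spheres are disjoint on the 1 mm template
  m1 <- make_sphere_mask(rois$centers["l_scr", ], 5, rois$grid_shape, 1)
  m2 <- make_sphere_mask(rois$centers["l_slf", ], 5, rois$grid_shape, 1)
  expect_equal(sum(m1 & m2), 0L)
  # scaled 2 mm version stays inside the reduced grid
  rois2 <- default_alps_rois(c(91, 109, 91), 2)
  expect_true(all(rois2$centers >= 0) &&
                all(sweep(rois2$centers, 2, c(91, 109, 91), "<")))
})
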