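# Independent oracles and small fixture builders shared across tests.

# brute-force sphere membership: enumerate the full cubic neighbourhood
oracle_sphere_count <- function(diameter_mm, voxel_size) {
  r <- diameter_mm / 2
  k <- ceiling(r / voxel_size) + 1
  g <- expand.grid(x = -k:k, y = -k:k, z = -k:k)
  sum((g$x^2 + g$y^2 + g$z^2) * voxel_size^2 <= r^2 + 1e-9)
}

# brute-force AUC: mean of the pairwise indicator over all pos-neg pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
}

# exhaustive threshold scan for the Youden point (classifier: score > t)
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, max(u))
  pos <- scores[labels]; neg <- scores[!labels]
  sens <- vapply(thr, function(t0) mean(pos > t0), numeric(1))
  spec <- vapply(thr, function(t0) mean(neg <= t0), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[which.max(spec[best])]
  list(threshold = thr[best], sensitivity = sens[best],
       specificity = spec[best], youden_j = j[best])
}

# textbook recursive partial-correlation formula for one covariate
oracle_partial_r <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# compact phantom on a 40 x 40 x 16 grid (2 mm voxels) with mirror-symmetric
# ROI centres (x -> 39 - x maps left onto right), fast enough for unit tests
small_phantom_setup <- function(proj_l = c(1.00, 0.68, 1.45) * 1e-3,
                                proj_r = proj_l,
                                assoc_l = c(0.82, 1.35, 0.68) * 1e-3,
                                assoc_r = assoc_l,
                                noise_sd = 0, seed = NULL, ...) {
  grid <- c(40L, 40L, 16L)
  centers <- rbind(l_scr = c(26, 20, 8), r_scr = c(13, 20, 8),
                   l_slf = c(33, 20, 8), r_slf = c(6, 20, 8))
  rois <- alps_rois(centers, grid, voxel_size = 2, diameter_mm = 5)
  mk <- function(nm, tensor)
    list(type = "box", center = centers[nm, ], halfwidth_mm = 5,
         tensor = tensor)
  regions <- list(l_scr = mk("l_scr", proj_l), r_scr = mk("r_scr", proj_r),
                  l_slf = mk("l_slf", assoc_l), r_slf = mk("r_slf", assoc_r))
  spec <- phantom_spec(grid_shape = grid, voxel_size = 2, regions = regions,
                       noise_sd = noise_sd, seed = seed, ...)
  list(spec = spec, rois = rois)
}

roi_union_mask <- function(rois) {
  m <- array(FALSE, rois$grid_shape)
  for (r in rownames(rois$centers))
    m <- m | make_sphere_mask(rois$centers[r, ], rois$diameter_mm,
                              rois$grid_shape, rois$voxel_size)
  m
}

pd_covariates <- c("age", "sex", "education", "duration", "hy")
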