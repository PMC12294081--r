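# Fixtures are built in code at test time; everything is deterministic
# given the seeds fixed in the tests.

# one cubic bone site (optionally with one spherical lesion) on a small grid
box_phantom_spec <- function(grid = c(40, 40, 40), spacing = 4.8,
                             lesion_radius_mm = NULL, with_kidneys = FALSE,
                             marrow = 25, background = 25) {
  fov <- grid * spacing
  ctr <- fov / 2
  sites <- list(list(type = "box", name = "vertebra_test",
                     center_mm = ctr, size_mm = c(60, 60, 60)))
  kidneys <- if (with_kidneys)
    list(list(type = "ellipsoid", center_mm = c(ctr[1], ctr[2] - 55, ctr[3]),
              semiaxes_mm = c(18, 14, 24)))
  else list()
  lesions <- if (!is.null(lesion_radius_mm))
    list(list(site = 1L, center_mm = ctr, radius_mm = lesion_radius_mm))
  else list()
  phantom_spec(grid_shape = grid, spacing_mm = spacing, site_geometry = sites,
               kidney_geometry = kidneys, lesion_spec = lesions,
               marrow_concentration_kBq_mL = marrow,
               background_concentration_kBq_mL = background,
               enforce_total_lesion_volume = FALSE)
}

# independent brute-force count of voxel centers inside a sphere
brute_force_sphere_count <- function(grid, spacing, center_mm, radius_mm) {
  n <- 0L
  for (i in seq_len(grid[1])) for (j in seq_len(grid[2])) for (k in seq_len(grid[3])) {
    p <- (c(i, j, k) - 0.5) * spacing
    if (sum((p - center_mm)^2) <= radius_mm^2) n <- n + 1L
  }
  n
}

# independent dense 3D convolution with a truncated normalized Gaussian,
# evaluated only at the requested voxels (oracle for blur-based RC values)
dense_gaussian_convolve_at <- function(arr, spacing, sigma_mm, at_idx) {
  r <- max(1L, ceiling(4 * sigma_mm / spacing))
  off <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  w <- exp(-0.5 * rowSums(off^2) * (spacing / sigma_mm)^2 / 1)
  # separable truncation must match a cubic support; normalize jointly
  w <- w / sum(w)
  d <- dim(arr)
  vals <- numeric(nrow(at_idx))
  for (q in seq_len(nrow(at_idx))) {
    pos <- sweep(off, 2, at_idx[q, ], `+`)
    ok <- pos[, 1] >= 1 & pos[, 1] <= d[1] & pos[, 2] >= 1 & pos[, 2] <= d[2] &
      pos[, 3] >= 1 & pos[, 3] <= d[3]
    # reflect out-of-range indices about the border (same boundary model)
    pr <- pos
    for (ax in 1:3) {
      pr[, ax] <- ifelse(pr[, ax] < 1, 1 - pr[, ax], pr[, ax])
      pr[, ax] <- ifelse(pr[, ax] > d[ax], 2 * d[ax] + 1 - pr[, ax], pr[, ax])
    }
    vals[q] <- sum(w * arr[cbind(pr[, 1], pr[, 2], pr[, 3])])
  }
  vals
}

# independent Dice coefficient from raw voxel sets
dice_coefficient <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
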