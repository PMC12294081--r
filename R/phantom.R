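# Virtual-patient voxel phantoms and the simplified imaging model.
#
# A phantom is a piecewise-constant reference activity map (kBq/mL) plus an
# integer label map of skeletal sites, kidneys and lesions. The imaging
# model standing in for the full SPECT simulation/reconstruction chain is
# an isotropic Gaussian system blur followed by optional voxelwise Poisson
# counting noise scaled by the acquisition time per projection.

# run code with a local, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic child-seed derivation so stages can be rerun in isolation
derive_seed <- function(seed, stream) {
  stream <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}

shape_mask <- function(shape, coords) {
  ctr <- shape$center_mm
  if (shape$type == "box") {
    h <- shape$size_mm / 2
    abs(coords$x - ctr[1]) <= h[1] & abs(coords$y - ctr[2]) <= h[2] &
      abs(coords$z - ctr[3]) <= h[3]
  } else if (shape$type == "ellipsoid") {
    a <- shape$semiaxes_mm
    ((coords$x - ctr[1]) / a[1])^2 + ((coords$y - ctr[2]) / a[2])^2 +
      ((coords$z - ctr[3]) / a[3])^2 <= 1
  } else if (shape$type == "sphere") {
    (coords$x - ctr[1])^2 + (coords$y - ctr[2])^2 + (coords$z - ctr[3])^2 <=
      shape$radius_mm^2
  } else stop("unknown shape type: ", shape$type)
}

# voxel-center coordinate arrays (mm from grid origin; voxel i center at (i-0.5)*spacing)
voxel_coords <- function(grid_shape, spacing_mm) {
  ax <- lapply(grid_shape, function(n) (seq_len(n) - 0.5) * spacing_mm)
  list(
    x = array(rep(ax[[1]], times = grid_shape[2] * grid_shape[3]), grid_shape),
    y = array(rep(rep(ax[[2]], each = grid_shape[1]), times = grid_shape[3]), grid_shape),
    z = array(rep(ax[[3]], each = grid_shape[1] * grid_shape[2]), grid_shape)
  )
}

#' Specification of a virtual-patient phantom
#'
#' Parametric geometry (boxes/ellipsoids for skeletal sites, two ellipsoids
#' for the kidneys, spherical lesions inside host sites) plus the activity
#' model: a lesion:kidney:background concentration ratio of 40:20:1 by
#' default, matching the mean ratio observed in Lu-177 PSMA patients, with
#' lesion-free marrow at a configurable concentration (default: background
#' level).
#'
#' @param grid_shape integer triple of voxel counts.
#' @param spacing_mm isotropic voxel spacing (mm).
#' @param site_geometry list of shapes, each
#'   `list(type = "box"|"ellipsoid", center_mm =, size_mm =|semiaxes_mm =, name =)`.
#' @param kidney_geometry list of two ellipsoid shapes.
#' @param lesion_spec list of `list(site =, center_mm =, radius_mm =)`.
#' @param activity_ratio lesion:kidney:background concentration ratio.
#' @param background_concentration_kBq_mL soft-tissue background level.
#' @param marrow_concentration_kBq_mL concentration in lesion-free bone.
#' @param enforce_total_lesion_volume if `TRUE` and lesions are present,
#'   [build_phantom()] rejects phantoms whose total lesion volume is not
#'   greater than 10 mL (the cohort inclusion criterion).
#' @param seed integer seed recorded with the phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64), spacing_mm = 4.8,
                         site_geometry = list(), kidney_geometry = list(),
                         lesion_spec = list(),
                         activity_ratio = c(40, 20, 1),
                         background_concentration_kBq_mL = 25,
                         marrow_concentration_kBq_mL = background_concentration_kBq_mL,
                         enforce_total_lesion_volume = TRUE,
                         seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 8), spacing_mm > 0,
            length(activity_ratio) == 3L, all(activity_ratio > 0),
            background_concentration_kBq_mL > 0, marrow_concentration_kBq_mL >= 0)
  structure(list(grid_shape = as.integer(grid_shape), spacing_mm = spacing_mm,
                 site_geometry = site_geometry, kidney_geometry = kidney_geometry,
                 lesion_spec = lesion_spec, activity_ratio = activity_ratio,
                 background_concentration_kBq_mL = background_concentration_kBq_mL,
                 marrow_concentration_kBq_mL = marrow_concentration_kBq_mL,
                 enforce_total_lesion_volume = enforce_total_lesion_volume,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Randomized virtual-patient phantom specification
#'
#' Draws one phantom from the cohort distribution: a simplified skeleton
#' (five stacked vertebra-like sites, a pelvis-like site, two femur-like
#' sites, plus distant humerus-like sites and a sternum-like site that stay
#' lesion free), two kidneys, and 2-5 spherical bone lesions (radius 7-14 mm)
#' placed fully inside randomly chosen lesion-eligible sites. Specs whose
#' total lesion volume does not exceed 10 mL are redrawn, mirroring the
#' cohort inclusion criterion.
#'
#' @param seed integer seed; the spec is a deterministic function of it.
#' @param grid_shape,spacing_mm grid geometry (defaults 64^3 at 4.8 mm).
#' @param n_lesions number of lesions, or `NULL` to draw 2-5.
#' @param ... passed on to [phantom_spec()].
#' @return a `phantom_spec`.
#' @export
sample_phantom_spec <- function(seed, grid_shape = c(64, 64, 64), spacing_mm = 4.8,
                                n_lesions = NULL, ...) {
  fov <- grid_shape * spacing_mm
  cx <- fov[1] / 2
  sites <- list()
  for (k in 0:4) {
    sites[[length(sites) + 1L]] <- list(type = "box", name = sprintf("vertebra_%d", k + 1),
      center_mm = c(cx, 0.65 * fov[2], 0.40 * fov[3] + k * 32),
      size_mm = c(30, 30, 26))
  }
  sites[[length(sites) + 1L]] <- list(type = "box", name = "pelvis",
    center_mm = c(cx, 0.60 * fov[2], 0.26 * fov[3]), size_mm = c(100, 45, 30))
  sites[[length(sites) + 1L]] <- list(type = "box", name = "femur_left",
    center_mm = c(cx - 50, 0.59 * fov[2], 0.10 * fov[3]), size_mm = c(26, 26, 50))
  sites[[length(sites) + 1L]] <- list(type = "box", name = "femur_right",
    center_mm = c(cx + 50, 0.59 * fov[2], 0.10 * fov[3]), size_mm = c(26, 26, 50))
  sites[[length(sites) + 1L]] <- list(type = "box", name = "humerus_left",
    center_mm = c(0.14 * fov[1], 0.52 * fov[2], 0.75 * fov[3]), size_mm = c(24, 24, 50))
  sites[[length(sites) + 1L]] <- list(type = "box", name = "humerus_right",
    center_mm = c(0.86 * fov[1], 0.52 * fov[2], 0.75 * fov[3]), size_mm = c(24, 24, 50))
  sites[[length(sites) + 1L]] <- list(type = "box", name = "sternum",
    center_mm = c(cx, 0.30 * fov[2], 0.65 * fov[3]), size_mm = c(26, 14, 60))
  kidneys <- list(
    list(type = "ellipsoid", center_mm = c(cx - 54, 0.46 * fov[2], 0.55 * fov[3]),
         semiaxes_mm = c(22, 16, 30)),
    list(type = "ellipsoid", center_mm = c(cx + 54, 0.46 * fov[2], 0.55 * fov[3]),
         semiaxes_mm = c(22, 16, 30)))
  eligible <- 1:8  # vertebrae, pelvis, femora may host lesions
  # voxel-counted sphere volume on the target grid (what build_phantom will see)
  vox_sphere_mL <- function(ctr, r) {
    lo <- pmax(floor((ctr - r) / spacing_mm), 0)
    hi <- pmin(ceiling((ctr + r) / spacing_mm), grid_shape - 1)
    g <- expand.grid(x = (lo[1]:hi[1]) + 0.5, y = (lo[2]:hi[2]) + 0.5,
                     z = (lo[3]:hi[3]) + 0.5)
    p <- as.matrix(g) * spacing_mm
    sum(rowSums(sweep(p, 2, ctr)^2) <= r^2) * spacing_mm^3 / 1000
  }
  with_seed(derive_seed(seed, "phantom-spec"), {
    repeat {
      nl <- if (is.null(n_lesions)) sample(2:5, 1) else n_lesions
      lesions <- list()
      total_mL <- 0
      for (j in seq_len(nl)) {
        repeat {
          host <- sample(eligible, 1)
          s <- sites[[host]]
          half <- s$size_mm / 2
          r <- stats::runif(1, 7, min(14, min(half) - 0.5))
          margin <- pmax(half - r, 0)
          ctr <- s$center_mm + stats::runif(3, -1, 1) * margin
          # lesions must not overlap (volumes add; no union shrinkage) and
          # must be at least 1 mL once voxelized
          clash <- any(vapply(lesions, function(L)
            sqrt(sum((L$center_mm - ctr)^2)) <= L$radius_mm + r, logical(1)))
          if (!clash && vox_sphere_mL(ctr, r) >= 1) break
        }
        lesions[[j]] <- list(site = host, center_mm = ctr, radius_mm = r)
        total_mL <- total_mL + vox_sphere_mL(ctr, r)
      }
      if (!is.null(n_lesions) && n_lesions == 0) break
      if (total_mL > 10) break
    }
    phantom_spec(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 site_geometry = sites, kidney_geometry = kidneys,
                 lesion_spec = lesions, seed = seed, ...)
  })
}

#' Build the reference activity map and label map from a spec
#'
#' Rasterizes the geometry on the voxel grid (voxel-center-inside-shape
#' rule) and paints the piecewise-constant reference activity: lesions at
#' `ratio[1]`, kidneys at `ratio[2]`, soft-tissue background at `ratio[3]`
#' times the background concentration, and lesion-free bone at the marrow
#' concentration. Construction is deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return `list(reference = voxel_image [kBq/mL], labels = site_label_map)`.
#'   Lesions smaller than 1 mL at the given spacing are rejected with a
#'   message naming the lesion, as are lesions not fully inside their host
#'   site, and (when `enforce_total_lesion_volume` is set) phantoms with
#'   total lesion volume of 10 mL or less.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  coords <- voxel_coords(d, spec$spacing_mm)
  vvol <- spec$spacing_mm^3 / 1000
  labels <- array(0L, d)
  n_sites <- length(spec$site_geometry)
  site_names <- character(n_sites)
  for (i in seq_len(n_sites)) {
    s <- spec$site_geometry[[i]]
    site_names[i] <- if (!is.null(s$name)) s$name else sprintf("site_%d", i)
    m <- shape_mask(s, coords)
    if (any(labels[m] != 0L))
      stop(sprintf("site '%s' overlaps a previously placed structure", site_names[i]))
    labels[m] <- i
  }
  kidney_labels <- integer(0)
  for (j in seq_along(spec$kidney_geometry)) {
    lab <- n_sites + j
    m <- shape_mask(spec$kidney_geometry[[j]], coords)
    if (any(labels[m] != 0L)) stop("kidney overlaps a previously placed structure")
    labels[m] <- lab
    kidney_labels <- c(kidney_labels, lab)
  }
  lesion_mask <- array(FALSE, d)
  total_lesion_mL <- 0
  for (j in seq_along(spec$lesion_spec)) {
    L <- spec$lesion_spec[[j]]
    m <- shape_mask(list(type = "sphere", center_mm = L$center_mm,
                         radius_mm = L$radius_mm), coords)
    vol <- sum(m) * vvol
    if (vol < 1)
      stop(sprintf("lesion %d (site %d): volume %.2f mL < 1 mL at %.2f mm spacing",
                   j, L$site, vol, spec$spacing_mm))
    if (any(labels[m] != L$site))
      stop(sprintf("lesion %d does not lie fully inside host site %d", j, L$site))
    lesion_mask <- lesion_mask | m
  }
  total_lesion_mL <- sum(lesion_mask) * vvol
  if (spec$enforce_total_lesion_volume && length(spec$lesion_spec) > 0 &&
      total_lesion_mL <= 10)
    stop(sprintf("total lesion volume %.1f mL does not exceed 10 mL", total_lesion_mL))

  bg <- spec$background_concentration_kBq_mL
  act <- array(bg * spec$activity_ratio[3], d)
  act[labels %in% seq_len(n_sites)] <- spec$marrow_concentration_kBq_mL
  act[labels %in% kidney_labels] <- bg * spec$activity_ratio[2]
  act[lesion_mask] <- bg * spec$activity_ratio[1]

  site_table <- data.frame(
    id = seq_len(n_sites), name = site_names,
    voxel_count = vapply(seq_len(n_sites), function(i) sum(labels == i), integer(1)))
  site_table$volume_mL <- site_table$voxel_count * vvol
  lm <- site_label_map(labels, lesion_mask, site_table, kidney_labels,
                       spec$spacing_mm)
  list(reference = voxel_image(act, spec$spacing_mm, "kBq/mL"), labels = lm)
}

#' Label map of skeletal sites, kidneys and lesions
#'
#' @param labels integer 3D array: 0 background, 1..K skeletal sites,
#'   further reserved labels for the kidneys.
#' @param lesion_mask logical 3D array; must lie inside skeletal sites.
#' @param site_table data frame with columns id, name, voxel_count, volume_mL.
#' @param kidney_labels integer labels reserved for the kidneys.
#' @param spacing_mm voxel spacing.
#' @return object of class `site_label_map`.
#' @export
site_label_map <- function(labels, lesion_mask, site_table,
                           kidney_labels = integer(0), spacing_mm = 4.8) {
  stopifnot(is.array(labels), length(dim(labels)) == 3L,
            identical(dim(labels), dim(lesion_mask)))
  in_sites <- labels %in% site_table$id
  if (any(lesion_mask & !in_sites))
    stop("lesion mask extends outside skeletal-site voxels")
  structure(list(labels = labels, lesion_mask = lesion_mask,
                 site_table = site_table, kidney_labels = kidney_labels,
                 spacing_mm = spacing_mm),
            class = "site_label_map")
}

#' @export
print.site_label_map <- function(x, ...) {
  cat(sprintf("<site_label_map> %d skeletal sites, %d kidney labels, %d lesion voxels\n",
              nrow(x$site_table), length(x$kidney_labels), sum(x$lesion_mask)))
  invisible(x)
}

#' Extract binary masks from a label map
#'
#' @param label_map a `site_label_map`.
#' @param id skeletal site id.
#' @return logical 3D array (`site_mask`: the site's voxels; `kidney_mask`:
#'   the union of kidney voxels, all-`FALSE` when no kidneys are present).
#' @export
site_mask <- function(label_map, id) label_map$labels == id

#' @rdname site_mask
#' @export
kidney_mask <- function(label_map) {
  if (length(label_map$kidney_labels) == 0) array(FALSE, dim(label_map$labels))
  else array(label_map$labels %in% label_map$kidney_labels, dim(label_map$labels))
}

#' Acquisition regime for the counting-noise model
#'
#' @param time_per_projection_s dwell time per projection (default 5 s,
#'   clinical regime; 15 s triples the expected counts).
#' @param poisson_noise apply Poisson counting noise?
#' @param counts_per_kBqmL_per_s calibration: expected counts per voxel per
#'   second per kBq/mL.
#' @param seed integer seed for the noise draw.
#' @param name optional label used in result tables.
#' @return object of class `acquisition_regime`.
#' @export
acquisition_regime <- function(time_per_projection_s = 5, poisson_noise = TRUE,
                               counts_per_kBqmL_per_s = 0.01, seed = 1L,
                               name = NULL) {
  stopifnot(time_per_projection_s > 0, counts_per_kBqmL_per_s > 0)
  if (is.null(name))
    name <- sprintf("%gs-%s", time_per_projection_s,
                    if (poisson_noise) "noise" else "clean")
  structure(list(time_per_projection_s = time_per_projection_s,
                 poisson_noise = isTRUE(poisson_noise),
                 counts_per_kBqmL_per_s = counts_per_kBqmL_per_s,
                 seed = as.integer(seed), name = name),
            class = "acquisition_regime")
}

#' Simplified imaging model: system blur plus Poisson counting noise
#'
#' Stand-in for the full projection/reconstruction chain: the reference
#' activity map is convolved with an isotropic Gaussian (the end-to-end
#' system PSF), then, if the regime has noise enabled, converted to expected
#' counts (value x calibration x time per projection), Poisson sampled, and
#' converted back to kBq/mL. Reproducible given the regime seed.
#'
#' @param reference `voxel_image` in kBq/mL.
#' @param psf_sigma_mm Gaussian sigma of the system PSF (>= 0); the package
#'   default corresponds to an 8.3 mm FWHM.
#' @param regime an [acquisition_regime()].
#' @return `voxel_image` in kBq/mL.
#' @export
image_forward_model <- function(reference, psf_sigma_mm = 8.3 / (2 * sqrt(2 * log(2))),
                                regime = acquisition_regime()) {
  stopifnot(is_voxel_image(reference), inherits(regime, "acquisition_regime"))
  if (reference$unit != "kBq/mL") stop("reference must be in kBq/mL")
  if (psf_sigma_mm < 0) stop("`psf_sigma_mm` must be >= 0")
  out <- gaussian_blur(reference, psf_sigma_mm)
  if (regime$poisson_noise) {
    scale <- regime$counts_per_kBqmL_per_s * regime$time_per_projection_s
    lam <- out$data * scale
    counts <- with_seed(regime$seed, stats::rpois(length(lam), lam))
    out <- with_data(out, array(counts / scale, dim(lam)))
  }
  out
}

#' Scale a phantom through time by per-tissue effective half-lives
#'
#' Each tissue compartment (lesion, kidney, marrow = lesion-free bone,
#' background) decays mono-exponentially with its own effective half-life;
#' used to produce the 24/48/72 h scan series for dosimetry.
#'
#' @param reference `voxel_image` at time 0 (kBq/mL).
#' @param label_map matching `site_label_map`.
#' @param effective_half_lives_h named list/vector with entries `lesion`,
#'   `kidney`, `marrow`, `background` (all > 0, in hours). Unknown names
#'   are rejected.
#' @param times_h non-negative acquisition times (hours post injection).
#' @return list of `voxel_image`, one per time point.
#' @export
generate_time_series <- function(reference, label_map, effective_half_lives_h,
                                 times_h) {
  stopifnot(is_voxel_image(reference), inherits(label_map, "site_label_map"),
            all(times_h >= 0))
  hl <- effective_half_lives_h
  known <- c("lesion", "kidney", "marrow", "background")
  if (is.null(names(hl)) || !all(names(hl) %in% known))
    stop("unknown tissue label in `effective_half_lives_h`; expected ",
         paste(known, collapse = ", "))
  if (!all(known %in% names(hl))) stop("half-life missing for some tissue")
  hl <- unlist(hl)[known]
  if (any(hl <= 0)) stop("half-lives must be > 0")
  in_site <- array(label_map$labels %in% label_map$site_table$id, dim(label_map$labels))
  comp <- list(lesion = label_map$lesion_mask,
               kidney = kidney_mask(label_map),
               marrow = in_site & !label_map$lesion_mask,
               background = !in_site & !kidney_mask(label_map))
  lapply(times_h, function(t) {
    arr <- reference$data
    for (nm in known) arr[comp[[nm]]] <- arr[comp[[nm]]] * 2^(-t / hl[[nm]])
    with_data(reference, arr)
  })
}

#' Six-sphere quality-control phantom (NEMA IEC style)
#'
#' Six spheres of the given diameters in a uniform background at the stated
#' sphere-to-background ratio (default 40:1, matching the lesion contrast),
#' arranged on a ring in the central plane. Used for matched-filter PSF
#' estimation and PVC iteration-selection sweeps.
#'
#' @param sphere_diameters_mm positive sphere diameters (defaults: standard
#'   10-37 mm set).
#' @param sphere_to_background_ratio concentration ratio (default 40).
#' @param background_kBq_mL background concentration.
#' @param grid_shape,spacing_mm grid geometry.
#' @param ring_radius_mm radius of the ring of sphere centers.
#' @return `list(reference = voxel_image, labels = site_label_map)` where
#'   sites 1..6 are the spheres. Overlapping spheres are rejected.
#' @export
build_nema_like_phantom <- function(sphere_diameters_mm = c(10, 13, 17, 22, 28, 37),
                                    sphere_to_background_ratio = 40,
                                    background_kBq_mL = 1,
                                    grid_shape = c(64, 64, 64), spacing_mm = 3.0,
                                    ring_radius_mm = 57) {
  stopifnot(all(sphere_diameters_mm > 0), sphere_to_background_ratio > 0)
  nsph <- length(sphere_diameters_mm)
  fov <- grid_shape * spacing_mm
  ang <- 2 * pi * (seq_len(nsph) - 1) / nsph
  centers <- cbind(fov[1] / 2 + ring_radius_mm * cos(ang),
                   fov[2] / 2 + ring_radius_mm * sin(ang),
                   fov[3] / 2)
  r <- sphere_diameters_mm / 2
  for (i in seq_len(nsph)) for (j in seq_len(nsph)) if (i < j) {
    if (sqrt(sum((centers[i, ] - centers[j, ])^2)) <= r[i] + r[j])
      stop("spheres overlap; increase ring radius or reduce diameters")
  }
  coords <- voxel_coords(grid_shape, spacing_mm)
  labels <- array(0L, grid_shape)
  for (i in seq_len(nsph)) {
    m <- shape_mask(list(type = "sphere", center_mm = centers[i, ],
                         radius_mm = r[i]), coords)
    labels[m] <- i
  }
  act <- array(background_kBq_mL, grid_shape)
  act[labels > 0] <- background_kBq_mL * sphere_to_background_ratio
  st <- data.frame(id = seq_len(nsph),
                   name = sprintf("sphere_%dmm", round(sphere_diameters_mm)),
                   voxel_count = vapply(seq_len(nsph), function(i) sum(labels == i),
                                        integer(1)))
  st$volume_mL <- st$voxel_count * spacing_mm^3 / 1000
  list(reference = voxel_image(act, spacing_mm, "kBq/mL"),
       labels = site_label_map(labels, array(FALSE, grid_shape), st,
                               integer(0), spacing_mm))
}
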