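# Lesion segmentation and construction of the assumed red-bone-marrow VOIs.
#
# Skeletal sites fall into three categories ("methods"): 1 = sites carrying
# bone lesions, 2 = lesion-free sites within 30 mm surface distance of a
# lesion, 3 = distant lesion-free sites. The assumed marrow VOI is the
# eroded bone compartment, excluding the dilated lesion mask where lesions
# are present: erosion trims the cortical margin, dilation guards the VOI
# against lesion spill-over.

#' Morphology and selection parameters for marrow VOI construction
#'
#' @param erosion_iterations erosion passes on the bone compartment (default 1).
#' @param dilation_iterations dilation passes on the lesion mask (default 1).
#' @param distance_threshold_mm neighboring/distant cutoff on the
#'   lesion-to-site surface distance (default 30 mm).
#' @param min_voi_volume_mL minimum VOI volume retained in analyses
#'   (default 1 mL; the sweeps use 1, 5, 15 mL).
#' @param connectivity structuring element: 6 (cross, default) or 26 (cube).
#' @return object of class `morphology_params`.
#' @export
morphology_params <- function(erosion_iterations = 1, dilation_iterations = 1,
                              distance_threshold_mm = 30, min_voi_volume_mL = 1,
                              connectivity = 6) {
  stopifnot(erosion_iterations >= 0, dilation_iterations >= 0,
            distance_threshold_mm > 0, min_voi_volume_mL >= 0,
            connectivity %in% c(6, 26))
  structure(list(erosion_iterations = erosion_iterations,
                 dilation_iterations = dilation_iterations,
                 distance_threshold_mm = distance_threshold_mm,
                 min_voi_volume_mL = min_voi_volume_mL,
                 connectivity = connectivity),
            class = "morphology_params")
}

#' Otsu threshold of a 1D sample
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' the sample range; ties are broken toward the lower bin edge. The
#' returned threshold is a bin edge; classes are `x <= t` vs `x > t`.
#'
#' @param values numeric vector with at least two distinct values.
#' @param n_bins histogram bins (default 256).
#' @return scalar threshold.
#' @export
otsu_threshold <- function(values, n_bins = 256) {
  values <- as.numeric(values)
  if (length(values) < 2 || diff(range(values)) == 0)
    stop("degenerate histogram: need at least two distinct values")
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- tabulate(pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L),
                     n_bins), nbins = n_bins)
  p <- h / sum(h)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  # between-class variance at each candidate split (class 0 = bins 1..k)
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(bcv)  # which.max takes the first (lowest edge) on ties
  edges[k + 1]
}

#' SUV image from an activity concentration image
#'
#' SUV = concentration (kBq/mL) x body mass (g) / injected activity (kBq),
#' i.e. decay-uncorrected standardized uptake value with body weight as the
#' normalizing mass.
#'
#' @param activity `voxel_image` in kBq/mL.
#' @param injected_activity_MBq injected activity in MBq (> 0).
#' @param body_mass_g body mass in grams (> 0).
#' @return unitless `voxel_image`.
#' @export
suv_from_activity <- function(activity, injected_activity_MBq, body_mass_g) {
  stopifnot(is_voxel_image(activity))
  if (activity$unit != "kBq/mL") stop("activity image must be in kBq/mL")
  if (injected_activity_MBq <= 0 || body_mass_g <= 0)
    stop("injected activity and body mass must be positive")
  suv <- activity$data * body_mass_g / (injected_activity_MBq * 1000)
  voxel_image(suv, activity$spacing_mm, "unitless")
}

#' Segment bone lesions: SUV prefilter then Otsu
#'
#' Within the bone compartments, voxels with SUV >= `suv_threshold` are
#' kept, an Otsu threshold is computed on the surviving values, and
#' connected components (26-connectivity) smaller than `min_lesion_vol_mL`
#' are removed. Mirrors the automated lesion segmentation of the clinical
#' workflow.
#'
#' @param suv unitless SUV `voxel_image` (see [suv_from_activity()]).
#' @param bone_labels `site_label_map`; only skeletal-site voxels are
#'   eligible.
#' @param suv_threshold SUV prefilter (default 2).
#' @param min_lesion_vol_mL minimum lesion component volume (default 1 mL).
#' @return logical lesion mask (subset of bone voxels). If no voxel
#'   survives the SUV prefilter an empty mask is returned with a warning.
#' @export
segment_lesions <- function(suv, bone_labels, suv_threshold = 2,
                            min_lesion_vol_mL = 1) {
  stopifnot(is_voxel_image(suv), inherits(bone_labels, "site_label_map"))
  if (suv$unit != "unitless")
    stop("`suv` must be a unitless SUV image; see suv_from_activity()")
  bone <- array(bone_labels$labels %in% bone_labels$site_table$id,
                dim(bone_labels$labels))
  if (!any(bone)) stop("bone label map is empty")
  cand <- bone & suv$data >= suv_threshold
  if (!any(cand)) {
    warning("no bone voxel reaches the SUV prefilter; returning empty lesion mask")
    return(array(FALSE, dim(suv$data)))
  }
  vals <- suv$data[cand]
  mask <- cand
  if (length(unique(vals)) > 1) {
    t_otsu <- otsu_threshold(vals)
    mask <- cand & suv$data > t_otsu
  }
  if (!any(mask)) return(mask)
  comp <- connected_components(mask, connectivity = 26)
  vvol <- voxel_volume_mL(suv)
  sizes <- tabulate(comp[comp > 0])
  keep <- which(sizes * vvol >= min_lesion_vol_mL)
  array(comp %in% keep & comp > 0, dim(comp))
}

#' Assumed red-bone-marrow VOI for one skeletal site
#'
#' VOI = eroded site mask, minus the dilated lesion mask. With an empty
#' lesion mask the VOI is simply the eroded site mask. An empty VOI is a
#' valid result (filtered later by the volume threshold).
#'
#' @param site_mask logical 3D array for the bone compartment.
#' @param lesion_mask logical 3D array (may be empty).
#' @param params [morphology_params()].
#' @return logical VOI mask.
#' @export
build_rbm_voi <- function(site_mask, lesion_mask = NULL, params = morphology_params()) {
  stopifnot(is.logical(site_mask), length(dim(site_mask)) == 3L)
  voi <- erode_mask(site_mask, params$erosion_iterations, params$connectivity)
  if (!is.null(lesion_mask) && any(lesion_mask)) {
    stopifnot_same_grid(site_mask, lesion_mask)
    les <- dilate_mask(lesion_mask, params$dilation_iterations, params$connectivity)
    voi <- voi & !les
  }
  voi
}

#' Classify skeletal sites into VOI methods 1-3
#'
#' Method 1: the site contains at least one lesion voxel. Method 2: the
#' lesion-free site's surface distance to the nearest lesion is at most the
#' distance threshold (default 30 mm). Method 3: all remaining (distant)
#' lesion-free sites. With an empty lesion mask every site is method 3.
#'
#' @param label_map `site_label_map`.
#' @param lesion_mask logical 3D array.
#' @param params [morphology_params()].
#' @return named integer vector, one method per site id.
#' @export
classify_sites <- function(label_map, lesion_mask, params = morphology_params()) {
  stopifnot(inherits(label_map, "site_label_map"))
  stopifnot_same_grid(label_map$labels, lesion_mask)
  ids <- label_map$site_table$id
  out <- stats::setNames(integer(length(ids)), ids)
  any_lesion <- any(lesion_mask)
  for (i in seq_along(ids)) {
    sm <- site_mask(label_map, ids[i])
    if (any(sm & lesion_mask)) { out[i] <- 1L; next }
    if (!any_lesion) { out[i] <- 3L; next }
    d <- surface_distance_mm(sm, lesion_mask, label_map$spacing_mm)
    out[i] <- if (d <= params$distance_threshold_mm) 2L else 3L
  }
  out
}

#' Evaluate a VOI on an activity image
#'
#' Mean concentration over the mask and total activity (mean x volume).
#' The record is flagged excluded when the VOI volume is below the
#' threshold (empty VOIs are always excluded).
#'
#' @param voi_mask logical 3D array.
#' @param image `voxel_image` in kBq/mL.
#' @param min_volume_mL inclusion threshold (default 1 mL).
#' @return list of class `voi_record`: `volume_mL`, `mean_kBq_mL`,
#'   `total_MBq`, `included`.
#' @export
evaluate_voi <- function(voi_mask, image, min_volume_mL = 1) {
  stopifnot(is_voxel_image(image))
  stopifnot_same_grid(voi_mask, image)
  n <- sum(voi_mask)
  vol <- n * voxel_volume_mL(image)
  if (n == 0L) {
    return(structure(list(volume_mL = 0, mean_kBq_mL = NA_real_,
                          total_MBq = NA_real_, included = FALSE),
                     class = "voi_record"))
  }
  mean_c <- mean(image$data[voi_mask])
  structure(list(volume_mL = vol, mean_kBq_mL = mean_c,
                 total_MBq = mean_c * vol / 1000,
                 included = vol >= min_volume_mL),
            class = "voi_record")
}
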