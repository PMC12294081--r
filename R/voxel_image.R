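#' 3D voxel image with isotropic spacing and a physical unit
#'
#' The basic container used throughout the package: a 3D numeric array with
#' an isotropic voxel spacing in mm and a unit tag. Activity images are in
#' kBq/mL, raw detector images in counts, SUV and masks are unitless.
#'
#' @param data 3D numeric array; all values finite. Activity images
#'   (`unit = "kBq/mL"`) must be non-negative.
#' @param spacing_mm positive scalar, isotropic voxel edge length in mm.
#' @param unit one of `"kBq/mL"`, `"counts"`, `"unitless"`.
#' @return An object of class `voxel_image`.
#' @examples
#' img <- voxel_image(array(1, c(8, 8, 8)), spacing_mm = 4.8, unit = "kBq/mL")
#' voxel_volume_mL(img)
#' @export
voxel_image <- function(data, spacing_mm, unit = c("kBq/mL", "counts", "unitless")) {
  unit <- match.arg(unit)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("voxel values must all be finite")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1L || spacing_mm <= 0)
    stop("`spacing_mm` must be a single positive number")
  if (unit %in% c("kBq/mL", "counts") && any(data < 0))
    stop(sprintf("images in %s must be non-negative", unit))
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm), unit = unit),
            class = "voxel_image")
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_image> %d x %d x %d @ %.3g mm [%s]\n",
              d[1], d[2], d[3], x$spacing_mm, x$unit))
  cat(sprintf("  range: %.4g .. %.4g\n", min(x$data), max(x$data)))
  invisible(x)
}

is_voxel_image <- function(x) inherits(x, "voxel_image")

#' Voxel volume in mL
#'
#' @param x a `voxel_image`, or a numeric spacing in mm.
#' @return Volume of one voxel in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_mL <- function(x) {
  s <- if (is_voxel_image(x)) x$spacing_mm else as.numeric(x)
  s^3 / 1000
}

# replace the data payload, keeping geometry/unit
with_data <- function(img, data, unit = img$unit) {
  voxel_image(data, img$spacing_mm, unit)
}

stopifnot_same_grid <- function(a, b) {
  da <- if (is_voxel_image(a)) dim(a$data) else dim(a)
  db <- if (is_voxel_image(b)) dim(b$data) else dim(b)
  if (!identical(da, db))
    stop("inputs are not on the same voxel grid")
  invisible(TRUE)
}

#' Total activity of an image or masked region
#'
#' Sum of the concentration values times the voxel volume. For a kBq/mL
#' image the result is in kBq; divide by 1000 for MBq.
#'
#' @param img a `voxel_image` in kBq/mL.
#' @param mask optional logical array selecting voxels.
#' @return total activity in kBq.
#' @export
total_activity_kBq <- function(img, mask = NULL) {
  v <- voxel_volume_mL(img)
  if (is.null(mask)) sum(img$data) * v else sum(img$data[mask]) * v
}

#' Write a voxel image as NIfTI with a JSON sidecar
#'
#' The image is written uncompressed (`.nii`) so that byte-level checksums
#' of repeated runs are comparable; a `.json` sidecar records spacing, unit
#' and any extra metadata.
#'
#' @param img a `voxel_image`.
#' @param path output path ending in `.nii`.
#' @param meta named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_voxel_image <- function(img, path, meta = list()) {
  stopifnot(is_voxel_image(img))
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- rep(img$spacing_mm, 3)
  RNifti::writeNifti(nii, path)
  sidecar <- c(list(spacing_mm = img$spacing_mm, unit = img$unit,
                    dim = dim(img$data)), meta)
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voxel image written by [write_voxel_image()]
#'
#' @param path path to the `.nii` file.
#' @return a `voxel_image`; unit is taken from the sidecar when present,
#'   otherwise `"unitless"`.
#' @export
read_voxel_image <- function(path) {
  nii <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(nii)[1]
  side <- paste0(tools::file_path_sans_ext(path), ".json")
  unit <- "unitless"
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$unit)) unit <- meta$unit
    if (!is.null(meta$spacing_mm)) sp <- meta$spacing_mm
  }
  voxel_image(array(as.numeric(nii), dim(nii)), sp, unit)
}
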