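#' Label identifiers for the six paraspinal muscles
#'
#' The fixed label convention used throughout the package: 0 is background and
#' 1--6 are the left/right multifidus, erector spinae, and psoas major.
#'
#' @return Named integer vector mapping muscle names to label IDs.
#' @export
paraseg_labels <- function() {
  c(background = 0L,
    multifidus_left = 1L, multifidus_right = 2L,
    erector_spinae_left = 3L, erector_spinae_right = 4L,
    psoas_left = 5L, psoas_right = 6L)
}

# label swap applied when a volume is mirrored along the left-right axis
mirror_label_map <- function() {
  c(0L, 2L, 1L, 4L, 3L, 6L, 5L)  # indexed by label + 1
}

#' Construct an image volume
#'
#' A 3D scalar intensity grid with physical voxel spacing. The axis convention
#' is fixed: x runs left to right, y posterior to anterior, z inferior to
#' superior (RAS).
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing Numeric length-3 vector, mm per voxel along (x, y, z).
#' @return An object of class `image_volume` with fields `data` and `spacing`.
#' @export
image_volume <- function(data, spacing) {
  data <- check_grid(data)
  spacing <- check_spacing(spacing)
  if (any(!is.finite(data))) stopf("image volume contains non-finite values")
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' Construct a label mask
#'
#' A 3D integer grid over the label IDs 0--6 (see [paraseg_labels()]), sharing
#' its geometry with a paired [image_volume()].
#'
#' @param data 3D array of integer labels in 0..6.
#' @param spacing Numeric length-3 vector, mm per voxel along (x, y, z).
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(data, spacing) {
  data <- check_grid(data)
  spacing <- check_spacing(spacing)
  vals <- unique(as.vector(data))
  if (any(!is.finite(vals)) || any(vals != round(vals)) || any(vals < 0 | vals > 6))
    stopf("mask contains labels outside {0..6}")
  storage.mode(data) <- "integer"
  structure(list(data = data, spacing = spacing), class = "label_mask")
}

check_grid <- function(data) {
  if (length(dim(data)) == 2) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 3) stopf("volume data must be a 3D array")
  if (any(dim(data) < 1)) stopf("every axis must have extent >= 1")
  data
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0))
    stopf("spacing must be three positive numbers (mm/voxel)")
  spacing
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(x$data, levels = 0:6))
  cat(sprintf("<label_mask> %s voxels @ %s mm; voxels per label: %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(sprintf("%d=%d", 0:6, as.integer(tab)), collapse = " ")))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' @export
dim.label_mask <- function(x) dim(x$data)

same_geometry <- function(a, b, tol = 1e-4) {
  identical(dim(a$data), dim(b$data)) && all(abs(a$spacing - b$spacing) < tol)
}

# ---- NIfTI input/output ----------------------------------------------------

read_nifti_volume <- function(path, reorient = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  if (reorient) {
    # honour the stored orientation by flipping/permuting to the RAS convention
    orient <- tryCatch(RNifti::orientation(img), error = function(e) NULL)
    if (!is.null(orient) && !is.na(orient) && nzchar(orient) && orient != "RAS") {
      RNifti::orientation(img) <- "RAS"
    }
  }
  sp <- RNifti::pixdim(img)[seq_len(3)]
  arr <- as.array(img)
  d <- dim(arr)[seq_len(min(3L, length(dim(arr))))]
  arr <- array(as.numeric(arr), c(d, rep(1L, 3 - length(d))))  # plain array
  list(data = arr, spacing = as.numeric(sp))
}

#' Read a paired image/mask NIfTI volume
#'
#' Loads an intensity volume and its label mask, verifies that the two share a
#' voxel grid and spacing, and validates the mask against the label convention
#' of [paraseg_labels()].
#'
#' @param image_path,mask_path Paths to NIfTI (.nii / .nii.gz) files.
#' @param reorient Reorient both volumes to the RAS axis convention when the
#'   file stores a full orientation (default TRUE).
#' @return A list with elements `image` ([image_volume()]) and `mask`
#'   ([label_mask()]).
#' @export
read_pair <- function(image_path, mask_path, reorient = TRUE) {
  img <- read_nifti_volume(image_path, reorient)
  msk <- read_nifti_volume(mask_path, reorient)
  if (!identical(dim(img$data), dim(msk$data)))
    stopf("geometry mismatch: image grid %s vs mask grid %s",
          paste(dim(img$data), collapse = "x"), paste(dim(msk$data), collapse = "x"))
  if (any(abs(img$spacing - msk$spacing) > 1e-3))
    stopf("geometry mismatch: image spacing (%s) vs mask spacing (%s)",
          paste(signif(img$spacing, 4), collapse = ", "),
          paste(signif(msk$spacing, 4), collapse = ", "))
  list(image = image_volume(img$data, img$spacing),
       mask = label_mask(msk$data, msk$spacing))
}

#' Write a volume to NIfTI
#'
#' Images are stored as 32-bit float, masks as 8-bit unsigned integer.
#'
#' @param vol An [image_volume()] or [label_mask()].
#' @param path Output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, c("image_volume", "label_mask")))
  dtype <- if (inherits(vol, "label_mask")) "uint8" else "float"
  img <- RNifti::asNifti(vol$data,
                         reference = list(pixdim = c(-1, vol$spacing, 0, 0, 0, 0)))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# ---- cohort manifests ------------------------------------------------------

#' Read or write a cohort manifest
#'
#' A manifest is a CSV with one row per subject and columns `id`, `image`,
#' `mask`; relative paths are resolved against the manifest's directory.
#'
#' @param path CSV file path.
#' @return Data frame with columns `id`, `image`, `mask`.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "image", "mask") %in% names(m)))
    stopf("manifest must have columns id, image, mask")
  base <- dirname(normalizePath(path))
  fix <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  m$image <- fix(m$image)
  m$mask <- fix(m$mask)
  m
}

#' @param manifest Data frame with columns `id`, `image`, `mask`.
#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[, c("id", "image", "mask")], path, row.names = FALSE)
  invisible(path)
}
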