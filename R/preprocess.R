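#' Resample a volume to a target voxel spacing
#'
#' Resamples onto the fixed pipeline grid (default 0.39 x 0.39 x 5 mm, the
#' spacing all volumes are brought to before training). The output grid has
#' `round(dim * spacing / target)` voxels per axis (at least one). Intensity
#' volumes are interpolated trilinearly; label masks use nearest-neighbour
#' interpolation so the label set is preserved. Sampling is voxel-centre
#' aligned with edge-replicate (border) padding.
#'
#' @param x An [image_volume()] or [label_mask()].
#' @param spacing Target spacing in mm/voxel, length 3.
#' @param ... Unused.
#' @return An object of the same class as `x` at the new spacing.
#' @export
resample <- function(x, spacing = c(0.39, 0.39, 5), ...) UseMethod("resample")

resample_grid <- function(data, spacing_in, spacing_out, nearest) {
  spacing_out <- check_spacing(spacing_out)
  scale <- spacing_out / spacing_in
  out_dim <- pmax(1L, as.integer(round(dim(data) * spacing_in / spacing_out)))
  A <- diag(scale)
  tvec <- 0.5 * scale - 0.5  # voxel-centre alignment
  storage.mode(data) <- "double"
  cpp_affine_resample(data, out_dim, A, tvec, nearest)
}

#' @rdname resample
#' @export
resample.image_volume <- function(x, spacing = c(0.39, 0.39, 5), ...) {
  out <- resample_grid(x$data, x$spacing, spacing, nearest = FALSE)
  image_volume(out, spacing)
}

#' @rdname resample
#' @export
resample.label_mask <- function(x, spacing = c(0.39, 0.39, 5), ...) {
  out <- resample_grid(x$data, x$spacing, spacing, nearest = TRUE)
  label_mask(out, spacing)
}

#' Per-subject intensity normalisation
#'
#' Rescales the intensity range of a volume linearly to \[0, 1\]: the minimum
#' maps to 0 and the maximum to 1. This is the per-subject preprocessing
#' applied before training and inference. A constant volume cannot be
#' rescaled; it is returned as all zeros with a warning.
#'
#' @param vol An [image_volume()].
#' @return The normalised [image_volume()].
#' @export
normalize_intensity <- function(vol) {
  stopifnot(inherits(vol, "image_volume"))
  rng <- range(vol$data)
  if (diff(rng) == 0) {
    warning("constant image: returning all zeros", call. = FALSE)
    return(image_volume(array(0, dim(vol$data)), vol$spacing))
  }
  image_volume((vol$data - rng[1]) / diff(rng), vol$spacing)
}
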