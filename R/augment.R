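#' Configuration for random affine + elastic augmentation
#'
#' Defaults follow the training protocol: scaling in -2.5..2.5%, left-right
#' mirroring, per-axis rotations in -2.5..2.5 degrees, translations of up to
#' 25 voxels in-plane and 2 voxels along z, and elastic deformation with
#' smoothing sigma 6--8 (voxels) and magnitude 50--100, all with border
#' (edge-replicate) padding.
#'
#' The elastic `magnitude` is a raw displacement-field scale: per-voxel
#' uniform noise in \[-1, 1\] is smoothed by a Gaussian of width `sigma`
#' voxels and then multiplied by `magnitude` (the convention of the reference
#' augmentation frameworks, which leave the unit unstated; after smoothing the
#' resulting displacements are on the order of a voxel).
#'
#' @param scale_range Isotropic scale-factor offset interval (fractions).
#' @param mirror_lr Probability of mirroring along the left-right axis.
#' @param rot_deg Per-axis rotation interval in degrees (applied about x, y, z
#'   through the volume centre, in physical mm space).
#' @param trans_vox_xy,trans_vox_z Translation intervals, expressed in voxels
#'   of the reference 0.39 x 0.39 x 5 mm grid (so they describe a physical
#'   shift — scanner-bed positioning variation — and are converted to each
#'   volume's own voxel size when applied).
#' @param elastic_sigma,elastic_magnitude Elastic deformation parameter
#'   intervals (see above).
#' @param elastic Logical: apply the elastic stage in [augment_dataset()].
#' @param n_out Target size of the augmented set (default 1000).
#' @param seed Integer seed for [augment_dataset()].
#' @return An `augment_config` list.
#' @export
augment_config <- function(scale_range = c(-0.025, 0.025),
                           mirror_lr = 0.5,
                           rot_deg = c(-2.5, 2.5),
                           trans_vox_xy = c(-25, 25),
                           trans_vox_z = c(-2, 2),
                           elastic_sigma = c(6, 8),
                           elastic_magnitude = c(50, 100),
                           elastic = TRUE,
                           n_out = 1000L,
                           seed = 0L) {
  chk_iv <- function(x) length(x) == 2 && x[1] <= x[2]
  stopifnot(chk_iv(scale_range), chk_iv(rot_deg), chk_iv(trans_vox_xy),
            chk_iv(trans_vox_z), chk_iv(elastic_sigma), chk_iv(elastic_magnitude),
            mirror_lr >= 0, mirror_lr <= 1)
  if (!is_count(n_out)) stopf("n_out must be a positive integer")
  structure(list(scale_range = scale_range, mirror_lr = mirror_lr,
                 rot_deg = rot_deg, trans_vox_xy = trans_vox_xy,
                 trans_vox_z = trans_vox_z, elastic_sigma = elastic_sigma,
                 elastic_magnitude = elastic_magnitude, elastic = isTRUE(elastic),
                 n_out = as.integer(n_out), seed = as.integer(seed)),
            class = "augment_config")
}

rot_mat <- function(ax, ay, az) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(ax), -sin(ax)), c(0, sin(ax), cos(ax)))
  Ry <- rbind(c(cos(ay), 0, sin(ay)), c(0, 1, 0), c(-sin(ay), 0, cos(ay)))
  Rz <- rbind(c(cos(az), -sin(az), 0), c(sin(az), cos(az), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

runifi <- function(iv) if (iv[1] == iv[2]) iv[1] else stats::runif(1, iv[1], iv[2])

#' Apply one random affine transform to an image/mask pair
#'
#' Samples a single affine (isotropic scale, optional left-right mirror,
#' small rotations about x/y/z through the volume centre, translation) and
#' applies it identically to the image (trilinear interpolation) and the mask
#' (nearest-neighbour), both with border padding. Rotations act in physical
#' (mm) space so anisotropic voxels are handled correctly. When the mirror is
#' applied, label IDs are remapped 1<->2, 3<->4, 5<->6 so anatomical
#' sidedness stays correct.
#'
#' Draws from the current RNG stream; seed externally (e.g. via
#' [augment_dataset()]) for reproducibility.
#'
#' @param img An [image_volume()].
#' @param msk The paired [label_mask()].
#' @param cfg An [augment_config()].
#' @param mirror Force the mirror on/off (logical), or NULL to randomise with
#'   probability `cfg$mirror_lr`.
#' @return List with transformed `image` and `mask`.
#' @export
random_affine <- function(img, msk, cfg = augment_config(), mirror = NULL) {
  stopifnot(inherits(img, "image_volume"), inherits(msk, "label_mask"))
  if (!same_geometry(img, msk)) stopf("image/mask geometry mismatch")
  nd <- dim(img$data)
  s <- 1 + runifi(cfg$scale_range)
  do_mirror <- if (is.null(mirror)) stats::runif(1) < cfg$mirror_lr else isTRUE(mirror)
  ang <- c(runifi(cfg$rot_deg), runifi(cfg$rot_deg), runifi(cfg$rot_deg)) * pi / 180
  # translations are specified on the reference 0.39/0.39/5 mm grid;
  # convert through mm to this volume's voxel size
  tr_mm <- c(runifi(cfg$trans_vox_xy) * 0.39, runifi(cfg$trans_vox_xy) * 0.39,
             runifi(cfg$trans_vox_z) * 5.0)
  tr <- tr_mm / img$spacing

  D <- diag(img$spacing)
  L_mm <- s * rot_mat(ang[1], ang[2], ang[3])
  L_vox <- solve(D) %*% L_mm %*% D
  M <- diag(c(if (do_mirror) -1 else 1, 1, 1))
  Fwd <- L_vox %*% M
  A <- solve(Fwd)              # output voxel -> source voxel (linear part)
  ctr <- (nd - 1) / 2
  tvec <- ctr - A %*% (ctr + tr)

  storage.mode(img$data) <- "double"
  mskd <- msk$data
  storage.mode(mskd) <- "double"
  out_img <- cpp_affine_resample(img$data, nd, A, as.numeric(tvec), FALSE)
  out_msk <- cpp_affine_resample(mskd, nd, A, as.numeric(tvec), TRUE)
  out_msk <- array(as.integer(round(out_msk)), nd)
  if (do_mirror) out_msk <- array(mirror_label_map()[out_msk + 1L], nd)
  out <- list(image = image_volume(out_img, img$spacing),
              mask = label_mask(out_msk, msk$spacing))
  attr(out, "transform") <- list(scale = s, mirror = do_mirror,
                                 angles_deg = ang * 180 / pi,
                                 translation_vox = as.numeric(tr))
  out
}

#' Apply one random elastic deformation to an image/mask pair
#'
#' A dense random displacement field (per-voxel uniform noise smoothed by a
#' Gaussian of width `sigma ~ U(elastic_sigma)` voxels, scaled by
#' `magnitude ~ U(elastic_magnitude)`) warps image and mask with the same
#' field; border padding; trilinear for the image, nearest for the mask.
#'
#' @inheritParams random_affine
#' @return List with warped `image` and `mask`.
#' @export
elastic_deform <- function(img, msk, cfg = augment_config()) {
  stopifnot(inherits(img, "image_volume"), inherits(msk, "label_mask"))
  if (!same_geometry(img, msk)) stopf("image/mask geometry mismatch")
  nd <- dim(img$data)
  sigma <- runifi(cfg$elastic_sigma)
  alpha <- runifi(cfg$elastic_magnitude)
  disp <- lapply(1:3, function(ax) {
    if (alpha == 0) return(array(0, nd))
    noise <- array(stats::runif(prod(nd), -1, 1), nd)
    alpha * cpp_gauss_smooth(noise, rep(sigma, 3))
  })
  storage.mode(img$data) <- "double"
  mskd <- msk$data
  storage.mode(mskd) <- "double"
  out_img <- cpp_warp_displacement(img$data, disp[[1]], disp[[2]], disp[[3]], FALSE)
  out_msk <- cpp_warp_displacement(mskd, disp[[1]], disp[[2]], disp[[3]], TRUE)
  list(image = image_volume(out_img, img$spacing),
       mask = label_mask(array(as.integer(round(out_msk)), nd), msk$spacing))
}

#' Expand a training manifest into a fixed-size augmented set
#'
#' Emits exactly `cfg$n_out` augmented image/mask pairs (default 1000),
#' cycling over source subjects uniformly, applying one random affine and —
#' when `cfg$elastic` — one elastic deformation per output. Deterministic
#' under `cfg$seed`.
#'
#' @param manifest Manifest data frame or CSV path (non-empty).
#' @param cfg An [augment_config()].
#' @param out_dir Output directory for the augmented NIfTI pairs and manifest.
#' @return The augmented manifest data frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
augment_dataset <- function(manifest, cfg = augment_config(), out_dir) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (nrow(manifest) < 1) stopf("manifest is empty")
  if (cfg$n_out < 1) stopf("n_out must be >= 1")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory: %s", out_dir)
  nsub <- nrow(manifest)
  cache <- new.env(parent = emptyenv())
  ids <- sprintf("aug-%04d", seq_len(cfg$n_out))
  img_paths <- file.path(out_dir, paste0(ids, "_img.nii.gz"))
  msk_paths <- file.path(out_dir, paste0(ids, "_msk.nii.gz"))
  src <- character(cfg$n_out)
  for (i in seq_len(cfg$n_out)) {
    j <- ((i - 1) %% nsub) + 1
    key <- manifest$id[j]
    if (is.null(cache[[key]]))
      cache[[key]] <- read_pair(manifest$image[j], manifest$mask[j])
    pair <- cache[[key]]
    out <- with_seed(derive_seed(cfg$seed, i), {
      p <- random_affine(pair$image, pair$mask, cfg)
      if (cfg$elastic) p <- elastic_deform(p$image, p$mask, cfg)
      p
    })
    write_volume(out$image, img_paths[i])
    write_volume(out$mask, msk_paths[i])
    src[i] <- key
  }
  aug <- data.frame(id = ids, image = img_paths, mask = msk_paths,
                    source = src, stringsAsFactors = FALSE)
  write.csv(aug, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  aug
}
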