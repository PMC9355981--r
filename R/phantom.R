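#' Configuration for the synthetic lumbar phantom
#'
#' Describes the synthetic axial volumes used to exercise and benchmark the
#' pipeline. Six bilaterally placed tube-like muscle regions (swept ellipses
#' with smooth per-slice radius modulation and centre jitter) are embedded in
#' a brighter body with a central bright vertebral-column-like structure.
#' Expected muscle volumes follow the cohort ordering erector spinae > psoas
#' major > multifidus; the per-muscle means are the cohort means (in ml)
#' rescaled so the muscles fill a fixed fraction of the phantom field of view.
#' The intensity model is: dark muscle + bright intramuscular fat speckle at a
#' per-subject fat fraction + brighter non-muscle surround + smooth
#' multiplicative bias field + additive Gaussian noise (T2-like contrast:
#' muscle is darker than fat).
#'
#' @param grid_shape Integer length-3 grid size, default `c(64, 64, 12)`.
#' @param spacing mm/voxel; default keeps the 5 mm slice thickness and scales
#'   the in-plane 0.39 mm resolution by the integer factor `256 / grid_shape[1]`.
#' @param mean_volume_ml Named expected per-muscle volumes in ml (names as in
#'   [paraseg_labels()]); by default the cohort means scaled to the phantom
#'   field of view with total muscle fill fraction `fill_fraction`.
#' @param fill_fraction Fraction of the field of view the six muscles occupy
#'   in expectation (default 0.12); used only when `mean_volume_ml` is NULL.
#' @param volume_cv Coefficient of variation of per-subject muscle volumes
#'   (default 0.25, matching the cohort's relative spread).
#' @param fat_fraction_range Interval in \[0, 1) for the per-subject bright
#'   fat speckle fraction inside muscle (default `c(0.05, 0.3)`).
#' @param bias_amplitude Relative amplitude of the smooth multiplicative bias
#'   field (default 0.2).
#' @param noise_sd Additive Gaussian noise SD relative to the unit-scale
#'   intensity model (default 0.03).
#' @param seed Integer cohort-level seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(grid_shape = c(64, 64, 12),
                           spacing = NULL,
                           mean_volume_ml = NULL,
                           fill_fraction = 0.12,
                           volume_cv = 0.25,
                           fat_fraction_range = c(0.05, 0.3),
                           bias_amplitude = 0.2,
                           noise_sd = 0.03,
                           seed = 0L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  if (is.null(spacing)) {
    k <- max(1, round(256 / grid_shape[1]))
    spacing <- c(0.39 * k, 0.39 * k, 5)
  }
  spacing <- check_spacing(spacing)
  if (is.null(mean_volume_ml)) {
    cohort <- cohort_mean_volumes_ml()
    fov_ml <- prod(grid_shape * spacing) / 1000
    mean_volume_ml <- cohort * (fill_fraction * fov_ml / sum(cohort))
  }
  if (is.null(names(mean_volume_ml)))
    names(mean_volume_ml) <- names(cohort_mean_volumes_ml())
  stopifnot(all(mean_volume_ml > 0), length(mean_volume_ml) == 6)
  stopifnot(length(fat_fraction_range) == 2,
            fat_fraction_range[1] >= 0, fat_fraction_range[2] < 1,
            fat_fraction_range[1] <= fat_fraction_range[2] ||
              (fat_fraction_range[1] == 0 && fat_fraction_range[2] == 0))
  stopifnot(noise_sd >= 0, bias_amplitude >= 0, volume_cv >= 0)
  structure(list(grid_shape = grid_shape, spacing = spacing,
                 mean_volume_ml = mean_volume_ml, volume_cv = volume_cv,
                 fat_fraction_range = as.numeric(fat_fraction_range),
                 bias_amplitude = bias_amplitude, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# mean muscle volumes (ml) of the reference cohort, by label 1..6
cohort_mean_volumes_ml <- function() {
  c(multifidus_left = 120.6, multifidus_right = 119.9,
    erector_spinae_left = 300.3, erector_spinae_right = 294.7,
    psoas_left = 157.3, psoas_right = 160.3)
}

# in-plane placement templates: centre (fraction of FOV, signed from midline;
# y positive = anterior) and ellipse aspect ratio rx/ry. Painted largest
# first so any contested voxels go to the larger muscle. The anatomy is kept
# compact (every muscle well inside the field of view, with z margins) so
# that the augmentation protocol's translations never push muscle out of the
# volume.
phantom_geometry <- function() {
  list(
    erector_spinae = list(labels = c(3L, 4L), cx = 0.17, cy = -0.10, aspect = 0.8),
    psoas          = list(labels = c(5L, 6L), cx = 0.10, cy =  0.09, aspect = 1.2),
    multifidus     = list(labels = c(1L, 2L), cx = 0.065, cy = -0.22, aspect = 0.65)
  )
}

# slice range occupied by muscle: the central ~70% of the stack, leaving
# z margins that absorb the augmentation protocol's through-plane shifts
phantom_z_range <- function(nz) {
  zm <- max(1L, round(0.15 * nz))
  if (nz - 2L * zm < 1L) zm <- max(0L, (nz - 1L) %/% 2L)
  seq(zm + 1L, nz - zm)
}

# longitudinal cross-section taper: muscle bellies are fusiform, widest
# mid-length and tapering toward their ends (also keeps the phantom's volume
# response smooth under small through-plane shifts: no flat end faces)
taper_profile_z <- function(nz, power = 1.2) {
  if (nz == 1) return(1)
  w <- pmax(0.3, sin(pi * (seq_len(nz) - 0.5) / nz)^power)
  w / mean(w)
}

# smooth 1D modulation along z: unit-mean positive curve
smooth_profile_z <- function(nz, amount = 0.2) {
  if (nz == 1) return(1)
  raw <- stats::rnorm(nz)
  if (nz >= 3) raw <- stats::filter(raw, rep(1 / 3, 3), circular = TRUE)
  raw <- as.numeric(raw)
  prof <- 1 + amount * raw / max(1e-9, stats::sd(raw))
  prof <- pmax(0.3, prof)
  prof / mean(prof)
}

#' Generate one synthetic phantom subject
#'
#' Deterministic given `(cfg, subject_seed)`. Returns a geometry-matched
#' image/mask pair; all six labels are guaranteed non-empty (an error is
#' raised if the grid is too small to place the six regions).
#'
#' @param cfg A [phantom_config()].
#' @param subject_seed Integer seed for this subject.
#' @return List with elements `image` ([image_volume()]) and `mask`
#'   ([label_mask()]).
#' @export
generate_phantom <- function(cfg, subject_seed = cfg$seed) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(subject_seed, generate_phantom_impl(cfg))
}

generate_phantom_impl <- function(cfg) {
  nd <- cfg$grid_shape
  sp <- cfg$spacing
  nx <- nd[1]; ny <- nd[2]; nz <- nd[3]
  fov <- nd * sp
  # physical coordinates of voxel centres, origin at the grid centre
  xs <- (seq_len(nx) - (nx + 1) / 2) * sp[1]
  ys <- (seq_len(ny) - (ny + 1) / 2) * sp[2]
  xg <- matrix(xs, nx, ny)
  yg <- matrix(ys, nx, ny, byrow = TRUE)

  mask <- array(0L, nd)
  slice_mm3 <- sp[3]                      # slab thickness per slice, mm
  zr <- phantom_z_range(nz)
  nz_eff <- length(zr)
  geom <- phantom_geometry()
  for (g in geom) {
    for (side in 1:2) {                   # 1 = left (negative x), 2 = right
      lab <- g$labels[side]
      vol_ml <- cfg$mean_volume_ml[[lab_name(lab)]] *
        max(0.2, 1 + cfg$volume_cv * stats::rnorm(1))
      area_mm2 <- vol_ml * 1000 / (nz_eff * slice_mm3)  # mean cross-section
      mod <- taper_profile_z(nz_eff) * smooth_profile_z(nz_eff)
      mod <- mod / mean(mod)
      sgn <- if (side == 1) -1 else 1
      cx0 <- sgn * g$cx * fov[1] + stats::rnorm(1, 0, 0.015 * fov[1])
      cy0 <- g$cy * fov[2] + stats::rnorm(1, 0, 0.015 * fov[2])
      jx <- smooth_profile_z(nz_eff, 0.1); jy <- smooth_profile_z(nz_eff, 0.1)
      rmod <- smooth_profile_z(nz_eff, 0.08)
      for (zi in seq_len(nz_eff)) {
        z <- zr[zi]
        a <- area_mm2 * mod[zi]
        rx <- sqrt(a * g$aspect / pi) * rmod[zi]
        ry <- sqrt(a / (g$aspect * pi)) / rmod[zi]
        cx <- cx0 + (jx[zi] - 1) * 15
        cy <- cy0 + (jy[zi] - 1) * 15
        inside <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
        sl <- mask[, , z]
        sl[inside & sl == 0L] <- lab
        mask[, , z] <- sl
      }
    }
  }
  # each labelled region must be one dense 6-connected component (slice
  # jitter or carving can occasionally pinch off slivers; drop them)
  for (lab in 1:6) {
    keep <- cpp_largest_component6(mask, lab)
    mask[mask == lab & !keep] <- 0L
  }
  counts <- tabulate(mask + 1L, nbins = 7L)[-1]
  if (any(counts == 0))
    stopf("grid %s too small to place all six muscle regions (empty label %s)",
          paste(nd, collapse = "x"), paste(which(counts == 0), collapse = ","))

  # intensity model (unit scale, T2-like: fat bright, muscle dark)
  img <- array(0.05, nd)                                  # air
  body <- ((xg - 0) / (0.36 * fov[1]))^2 + ((yg + 0.04 * fov[2]) / (0.38 * fov[2]))^2 <= 1
  spine <- (xg^2 + (yg + 0.04 * fov[2])^2) <= (0.07 * fov[1])^2
  for (z in seq_len(nz)) {
    sl <- img[, , z]
    sl[body] <- 0.55
    sl[spine] <- 0.75
    img[, , z] <- sl
  }
  img[mask > 0L] <- 0.35

  # bright intramuscular fat speckle: spatially correlated streaks obtained by
  # thresholding smoothed noise inside the muscle mask at the quantile implied
  # by the per-subject fat fraction
  ff <- if (diff(cfg$fat_fraction_range) > 0)
    stats::runif(1, cfg$fat_fraction_range[1], cfg$fat_fraction_range[2])
  else cfg$fat_fraction_range[1]
  if (ff > 0) {
    noise <- array(stats::rnorm(prod(nd)), nd)
    sig_vox <- pmax(0.5, 2 / sp)  # ~2 mm correlation length
    field <- cpp_gauss_smooth(noise, sig_vox)
    inm <- mask > 0L
    thr <- stats::quantile(field[inm], 1 - ff)
    img[inm & field > thr] <- 0.85
  }

  # smooth multiplicative bias field
  if (cfg$bias_amplitude > 0) {
    g0 <- array(stats::rnorm(prod(nd)), nd)
    field <- cpp_gauss_smooth(g0, pmax(1, 0.4 * nd))
    field <- field / max(abs(field))
    img <- img * (1 + cfg$bias_amplitude * field)
  }
  if (cfg$noise_sd > 0)
    img <- img + stats::rnorm(prod(nd), 0, cfg$noise_sd)

  list(image = image_volume(img * 600, sp),   # arbitrary scanner-like units
       mask = label_mask(mask, sp))
}

lab_name <- function(lab) names(paraseg_labels())[match(lab, paraseg_labels())]

#' Generate a synthetic cohort on disk
#'
#' Writes `n` phantom image/mask NIfTI pairs plus a CSV manifest. Subject
#' seeds are derived deterministically from `(seed, index)`, so two runs with
#' the same arguments produce byte-identical volumes.
#'
#' @param n Number of subjects (>= 1).
#' @param cfg A [phantom_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Cohort seed; defaults to `cfg$seed`.
#' @return The manifest data frame (columns `id`, `image`, `mask`), invisibly
#'   also written to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n, cfg = phantom_config(), out_dir, seed = cfg$seed) {
  stopifnot(is_count(n))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory: %s", out_dir)
  ids <- sprintf("sub-%03d", seq_len(n))
  img_paths <- file.path(out_dir, paste0(ids, "_img.nii.gz"))
  msk_paths <- file.path(out_dir, paste0(ids, "_msk.nii.gz"))
  for (i in seq_len(n)) {
    ph <- generate_phantom(cfg, derive_seed(seed, i))
    write_volume(ph$image, img_paths[i])
    write_volume(ph$mask, msk_paths[i])
  }
  manifest <- data.frame(id = ids, image = img_paths, mask = msk_paths,
                         stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Load a cohort into memory
#'
#' Reads every manifest row with [read_pair()].
#'
#' @param manifest Manifest data frame or path to a manifest CSV.
#' @return Named list of `list(image, mask)` pairs.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  pairs <- lapply(seq_len(nrow(manifest)), function(i)
    read_pair(manifest$image[i], manifest$mask[i]))
  names(pairs) <- manifest$id
  pairs
}
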