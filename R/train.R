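#' Training configuration
#'
#' Defaults follow the study protocol at full scale: AdamW (learning rate
#' 0.001, decoupled weight decay 0.0001) on the Dice + cross-entropy loss for
#' 30,000 iterations; spatial windows of 256 x 256 x 1 (2D, squeezed) or
#' 256 x 256 x 32 (3D); effective batch sizes 50 (2D, 4 windows per loaded
#' volume) and 10 (3D, 1 window per volume); window centres drawn from
#' foreground/background voxels at a positive/negative ratio of 1; seed 0.
#' Scale `iterations`, `window`, and `batch_size` down for desk-scale runs.
#'
#' @param dims 2 or 3; sets window/batch defaults.
#' @param iterations Number of optimiser iterations.
#' @param window Spatial window `(x, y, z)`; z must be 1 for 2D.
#' @param batch_size Windows per iteration.
#' @param num_samples Windows sampled per loaded volume.
#' @param learning_rate,weight_decay AdamW hyper-parameters.
#' @param pos_neg_ratio Foreground:background ratio of window centres.
#' @param smooth Dice smoothing term.
#' @param seed Deterministic seed for sampling order (weight init uses the
#'   network config's seed).
#' @param log_every Iterations between loss-log records.
#' @return A `train_config` list.
#' @export
train_config <- function(dims = 2,
                         iterations = 30000L,
                         window = NULL,
                         batch_size = NULL,
                         num_samples = NULL,
                         learning_rate = 0.001,
                         weight_decay = 0.0001,
                         pos_neg_ratio = 1,
                         smooth = 1e-5,
                         seed = 0L,
                         log_every = 25L) {
  if (!dims %in% c(2, 3)) stopf("dims must be 2 or 3")
  if (is.null(window)) window <- if (dims == 2) c(256L, 256L, 1L) else c(256L, 256L, 32L)
  if (is.null(batch_size)) batch_size <- if (dims == 2) 50L else 10L
  if (is.null(num_samples)) num_samples <- if (dims == 2) 4L else 1L
  window <- as.integer(window)
  stopifnot(length(window) == 3, all(window >= 1))
  if (dims == 2 && window[3] != 1) stopf("2D training windows must have z extent 1")
  stopifnot(is_count(iterations), is_count(batch_size), is_count(num_samples),
            learning_rate > 0, weight_decay >= 0, pos_neg_ratio >= 0)
  structure(list(dims = as.integer(dims), iterations = as.integer(iterations),
                 window = window, batch_size = as.integer(batch_size),
                 num_samples = as.integer(num_samples),
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 pos_neg_ratio = pos_neg_ratio, smooth = smooth,
                 seed = as.integer(seed), log_every = as.integer(log_every)),
            class = "train_config")
}

#' Subject-level k-fold split
#'
#' Shuffles subjects deterministically by seed and assigns them to k folds
#' whose test sets differ in size by at most one; every subject tests exactly
#' once.
#'
#' @param subject_ids Character or integer vector of ids.
#' @param k Number of folds (>= 2, <= number of subjects).
#' @param seed Shuffle seed.
#' @return List of `fold_split` lists with `fold_index`, `train_ids`,
#'   `test_ids`.
#' @export
kfold_split <- function(subject_ids, k, seed = 0L) {
  n <- length(subject_ids)
  if (!is_count(k) || k < 2) stopf("k must be an integer >= 2")
  if (k > n) stopf("k (%d) exceeds the number of subjects (%d)", k, n)
  perm <- with_seed(seed, sample(n))
  fold_of <- rep(seq_len(k), length.out = n)
  lapply(seq_len(k), function(f) {
    test <- subject_ids[perm[fold_of == f]]
    structure(list(fold_index = f,
                   train_ids = setdiff(subject_ids, test),
                   test_ids = test),
              class = "fold_split")
  })
}

# clamp-indexed crop: windows reaching past the volume edge are border-padded
crop_window <- function(arr, centre, window) {
  nd <- dim(arr)
  idx <- lapply(1:3, function(ax) {
    start <- centre[ax] - (window[ax] %/% 2)
    pmin(pmax(seq(start, length.out = window[ax]), 1L), nd[ax])
  })
  arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' Sample training windows from a volume
#'
#' Draws `cfg$num_samples` windows whose centre voxel is a foreground voxel
#' (any label > 0) with probability `ratio / (ratio + 1)` and a background
#' voxel otherwise; crops exceeding the volume bounds are border-padded. A
#' mask without foreground yields all-background centres with a warning.
#' Draws from the current RNG stream.
#'
#' @param img An [image_volume()] (already normalised).
#' @param msk The paired [label_mask()].
#' @param cfg A [train_config()].
#' @return List of `list(image, label)` window arrays of dim `cfg$window`.
#' @export
sample_windows <- function(img, msk, cfg) {
  if (!same_geometry(img, msk)) stopf("image/mask geometry mismatch")
  nd <- dim(img$data)
  fg <- which(msk$data > 0L)
  bg <- which(msk$data == 0L)
  if (length(fg) == 0) warning("mask has no foreground voxels", call. = FALSE)
  p_fg <- cfg$pos_neg_ratio / (cfg$pos_neg_ratio + 1)
  lapply(seq_len(cfg$num_samples), function(i) {
    pool <- if ((length(fg) > 0 && stats::runif(1) < p_fg) || length(bg) == 0) fg else bg
    v <- pool[sample.int(length(pool), 1L)] - 1L
    ctr <- c(v %% nd[1], (v %/% nd[1]) %% nd[2], v %/% (nd[1] * nd[2])) + 1L
    list(image = crop_window(img$data, ctr, cfg$window),
         label = crop_window(msk$data, ctr, cfg$window))
  })
}

#' Dice + cross-entropy loss
#'
#' The training loss: soft Dice (1 minus the channel-mean soft Dice of the
#' softmax probabilities against the one-hot labels, with smoothing term
#' `smooth` in numerator and denominator) plus the voxel-mean cross-entropy.
#'
#' @param scores Class-score array whose last dimension indexes the classes
#'   (e.g. `(nx, ny, C)` or a `(C, N)` matrix with `channels_first = TRUE`).
#' @param labels Integer array of true labels in `0..C-1`, matching the
#'   spatial layout of `scores`.
#' @param smooth Dice smoothing term (default 1e-5).
#' @param channels_first Set TRUE when `scores` is already `(C, N)`.
#' @return Scalar loss with attributes `dice_loss` and `ce_loss`.
#' @export
dice_ce_loss <- function(scores, labels, smooth = 1e-5, channels_first = FALSE) {
  if (channels_first) {
    sm <- as.matrix(scores)
  } else {
    d <- dim(scores)
    if (is.null(d)) stopf("scores must be an array")
    C <- d[length(d)]
    n <- prod(d[-length(d)])
    sm <- t(matrix(as.numeric(scores), n, C))
  }
  lab <- as.integer(labels)
  if (length(lab) != ncol(sm))
    stopf("labels (%d values) do not match scores (%d voxels)", length(lab), ncol(sm))
  r <- cpp_dice_ce(sm, lab, smooth)
  structure(r$loss, dice_loss = r$dice_loss, ce_loss = r$ce_loss)
}

# assemble a batch of windows from preloaded pairs into engine arrays
assemble_batch <- function(pairs, cfg) {
  nvol <- max(1L, round(cfg$batch_size / cfg$num_samples))
  take <- sample.int(length(pairs), nvol, replace = TRUE)
  wins <- unlist(lapply(take, function(i)
    sample_windows(pairs[[i]]$image, pairs[[i]]$mask, cfg)), recursive = FALSE)
  nb <- length(wins)
  w <- cfg$window
  x <- array(0, c(w, 1L, nb))
  y <- array(0L, c(w, nb))
  for (i in seq_len(nb)) {
    x[, , , 1L, i] <- wins[[i]]$image
    y[, , , i] <- wins[[i]]$label
  }
  list(x = x, y = y)
}

#' Train a modified U-Net
#'
#' Runs AdamW on the Dice + cross-entropy loss over randomly sampled window
#' batches. All randomness (window sampling, volume order) derives from
#' `train_cfg$seed` and weight initialisation from `unet_cfg$seed`, so a run
#' is fully reproducible on a given numeric backend. Images are intensity
#' normalised per subject on load. Training aborts with a diagnostic if the
#' loss becomes non-finite.
#'
#' @param data A manifest data frame / CSV path, or a list of
#'   `list(image, mask)` pairs.
#' @param unet_cfg A [unet_config()].
#' @param train_cfg A [train_config()] (dims must agree).
#' @param verbose Print loss every `log_every` iterations.
#' @return A checkpoint: `unet_model` fields plus `train_cfg` and a
#'   `loss_log` data frame (iteration, loss, dice_loss, ce_loss).
#' @export
train_model <- function(data, unet_cfg, train_cfg, verbose = FALSE) {
  stopifnot(inherits(unet_cfg, "unet_config"), inherits(train_cfg, "train_config"))
  if (unet_cfg$dims != train_cfg$dims) stopf("network/training dims mismatch")
  pairs <- if (is.list(data) && !is.data.frame(data)) data else load_cohort(data)
  if (length(pairs) == 0) stopf("no training subjects")
  pairs <- lapply(pairs, function(p)
    list(image = normalize_intensity(p$image), mask = p$mask))
  model <- build_unet(unet_cfg)
  cfg_cpp <- cfg_for_cpp(unet_cfg)
  np <- length(model$params)
  m <- numeric(np); v <- numeric(np)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  lr <- train_cfg$learning_rate; wd <- train_cfg$weight_decay
  log_it <- integer(0); log_loss <- log_dice <- log_ce <- numeric(0)
  params <- model$params
  with_seed(train_cfg$seed, {
    for (it in seq_len(train_cfg$iterations)) {
      b <- assemble_batch(pairs, train_cfg)
      r <- cpp_unet_loss_grad(cfg_cpp, params, b$x, as.integer(b$y), train_cfg$smooth)
      if (!is.finite(r$loss))
        stopf("training diverged at iteration %d (loss = %g)", it, r$loss)
      g <- r$grad
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mh <- m / (1 - b1^it)
      vh <- v / (1 - b2^it)
      params <- params - lr * (mh / (sqrt(vh) + adam_eps) + wd * params)
      if (it == 1 || it %% train_cfg$log_every == 0 || it == train_cfg$iterations) {
        log_it <- c(log_it, it); log_loss <- c(log_loss, r$loss)
        log_dice <- c(log_dice, r$dice_loss); log_ce <- c(log_ce, r$ce_loss)
        if (verbose)
          message(sprintf("iter %6d  loss %.4f (dice %.4f, ce %.4f)",
                          it, r$loss, r$dice_loss, r$ce_loss))
      }
    }
  })
  structure(list(cfg = unet_cfg, params = params, layout = model$layout,
                 train_cfg = train_cfg,
                 loss_log = data.frame(iteration = log_it, loss = log_loss,
                                       dice_loss = log_dice, ce_loss = log_ce)),
            class = c("paraseg_checkpoint", "unet_model"))
}

#' Predict a full-volume segmentation
#'
#' 2D models segment a volume slice by slice on full (padded) slices; 3D
#' models run sliding windows of the training window size with 50% overlap
#' along z and uniform mean score blending. Spatial extents are padded by
#' edge replication to the network's divisibility requirement and cropped
#' back. The per-voxel label is the arg-max score channel, ties broken by the
#' lowest label ID. The image is intensity normalised per subject before
#' inference.
#'
#' @param checkpoint A trained checkpoint from [train_model()] (or any
#'   `unet_model`, with `window` supplied for 3D).
#' @param img An [image_volume()] resampled as in training.
#' @param window 3D sliding-window size; defaults to the checkpoint's
#'   training window.
#' @param slices_per_batch Number of 2D slices evaluated per forward pass.
#' @return A [label_mask()] of predicted labels.
#' @export
predict_volume <- function(checkpoint, img, window = NULL, slices_per_batch = 8L) {
  stopifnot(inherits(img, "image_volume"))
  cfg <- checkpoint$cfg
  img <- normalize_intensity(img)
  nd <- dim(img$data)
  mdiv <- 2^(length(cfg$channels) - 1)
  pad_to <- function(n) as.integer(ceiling(n / mdiv) * mdiv)
  px <- pad_to(nd[1]); py <- pad_to(nd[2])
  ix <- pmin(seq_len(px), nd[1]); iy <- pmin(seq_len(py), nd[2])
  C <- cfg$out_channels
  if (cfg$dims == 2) {
    scores <- array(0, c(nd[1], nd[2], nd[3], C))
    zs <- seq_len(nd[3])
    for (grp in split(zs, ceiling(zs / slices_per_batch))) {
      nb <- length(grp)
      x <- array(0, c(px, py, 1L, 1L, nb))
      for (i in seq_len(nb)) x[, , 1L, 1L, i] <- img$data[ix, iy, grp[i]]
      s <- cpp_unet_forward(cfg_for_cpp(cfg), checkpoint$params, x)
      for (i in seq_len(nb))
        scores[, , grp[i], ] <- s[seq_len(nd[1]), seq_len(nd[2]), 1L, , i]
    }
  } else {
    if (is.null(window)) window <- checkpoint$train_cfg$window
    if (is.null(window)) stopf("a 3D window size is required")
    wz <- pad_to(window[3])
    starts <- if (nd[3] <= wz) 1L else {
      s <- seq(1L, nd[3] - wz + 1L, by = max(1L, wz %/% 2L))
      unique(c(s, nd[3] - wz + 1L))
    }
    acc <- array(0, c(nd[1], nd[2], nd[3], C))
    cnt <- array(0, c(nd[1], nd[2], nd[3]))
    for (z0 in starts) {
      iz <- pmin(seq(z0, length.out = wz), nd[3])
      x <- array(img$data[ix, iy, iz], c(px, py, wz, 1L, 1L))
      s <- cpp_unet_forward(cfg_for_cpp(cfg), checkpoint$params, x)
      zr <- z0:min(nd[3], z0 + wz - 1L)
      sz <- seq_along(zr)
      sl <- array(s[seq_len(nd[1]), seq_len(nd[2]), sz, , 1L, drop = FALSE],
                  c(nd[1], nd[2], length(sz), C))
      acc[, , zr, ] <- array(acc[, , zr, , drop = FALSE],
                             c(nd[1], nd[2], length(zr), C)) + sl
      cnt[, , zr] <- cnt[, , zr] + 1
    }
    scores <- acc / as.vector(cnt)
  }
  flat <- matrix(scores, prod(nd), C)
  lab <- max.col(flat, ties.method = "first") - 1L
  label_mask(array(as.integer(lab), nd), img$spacing)
}
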