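test_that("kfold_split partitions subjects with balanced fold sizes", {
  ids <- sprintf("s%02d", 1:76)
  folds <- kfold_split(ids, k = 3, seed = 0)
  sizes <- sort(vapply(folds, function(f) length(f$test_ids), 1L), decreasing = TRUE)
  expect_equal(sizes, c(26L, 25L, 25L))
  # every subject tests exactly once; train/test disjoint
  all_test <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_setequal(all_test, ids)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(intersect(f$train_ids, f$test_ids), 0)
    expect_setequal(c(f$train_ids, f$test_ids), ids)
  }
  # determinism and seed sensitivity
  expect_identical(kfold_split(ids, 3, seed = 0), folds)
  expect_false(identical(kfold_split(ids, 3, seed = 1)[[1]]$test_ids,
                         folds[[1]]$test_ids))
  # small balanced case and error cases
  f6 <- kfold_split(letters[1:6], 3, seed = 2)
  expect_equal(vapply(f6, function(f) length(f$test_ids), 1L), rep(2L, 3))
  expect_error(kfold_split(letters[1:3], 4), "exceeds")
})

test_that("sample_windows balances foreground and background centres", {
  p <- test_cohort(1)[[1]]
  cfg <- train_config(dims = 2, iterations = 1, window = c(32, 32, 1),
                      batch_size = 1, num_samples = 1, seed = 0)
  img <- normalize_intensity(p$image)
  # windows have the requested shape
  set.seed(1)
  w <- sample_windows(img, p$mask, cfg)
  expect_length(w, 1)
  expect_identical(dim(w[[1]]$image), c(32L, 32L, 1L))
  expect_identical(dim(w[[1]]$label), c(32L, 32L, 1L))

  # binomial check of the positive/negative ratio on a half-foreground mask
  half <- array(0L, c(20, 20, 2)); half[1:10, , ] <- 1L
  hm <- label_mask(half, c(1, 1, 1))
  hi <- image_volume(array(0.5, c(20, 20, 2)), c(1, 1, 1))
  cfg2 <- train_config(dims = 2, iterations = 1, window = c(4, 4, 1),
                       batch_size = 1, num_samples = 1, seed = 0)
  set.seed(2)
  centres_fg <- replicate(10000, {
    w <- sample_windows(hi, hm, cfg2)[[1]]
    w$label[3, 3, 1] == 1L    # centre voxel of a 4x4 window
  })
  expect_equal(mean(centres_fg), 0.5, tolerance = 0.02)

  # all-foreground mask: every centre is foreground
  fullm <- label_mask(array(1L, c(8, 8, 1)), c(1, 1, 1))
  fulli <- image_volume(array(0.1, c(8, 8, 1)), c(1, 1, 1))
  set.seed(3)
  w <- sample_windows(fulli, fullm, cfg2)
  expect_true(all(w[[1]]$label == 1L))

  # no-foreground mask warns and falls back to background centres
  emptym <- label_mask(array(0L, c(8, 8, 1)), c(1, 1, 1))
  expect_warning(sample_windows(fulli, emptym, cfg2), "foreground")
})

test_that("dice_ce_loss has the expected closed-form behaviour", {
  set.seed(4)
  n <- 50
  labels <- sample(0:6, n, replace = TRUE)
  # uniform scores: the cross-entropy term is exactly ln 7 per voxel
  uni <- matrix(0, 7, n)
  l_uni <- dice_ce_loss(uni, labels, channels_first = TRUE)
  expect_equal(attr(l_uni, "ce_loss"), log(7), tolerance = 1e-5)

  # strongly peaked on the truth: loss tends to 0
  peaked <- matrix(-50, 7, n)
  peaked[cbind(labels + 1, seq_len(n))] <- 50
  l_peak <- dice_ce_loss(peaked, labels, channels_first = TRUE)
  expect_lt(as.numeric(l_peak), 1e-3)

  # permuting voxels leaves the loss unchanged
  perm <- sample(n)
  l_perm <- dice_ce_loss(uni[, perm], labels[perm], channels_first = TRUE)
  expect_equal(as.numeric(l_perm), as.numeric(l_uni), tolerance = 1e-6)

  # array (spatial-last-channel) interface agrees with channels-first
  sc <- array(rnorm(8 * 8 * 7), c(8, 8, 7))
  lab2 <- array(sample(0:6, 64, TRUE), c(8, 8))
  a <- dice_ce_loss(sc, lab2)
  b <- dice_ce_loss(t(matrix(sc, 64, 7)), as.integer(lab2), channels_first = TRUE)
  expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-6)

  expect_error(dice_ce_loss(uni, labels[-1], channels_first = TRUE), "match")
})

test_that("the analytic loss gradient matches finite differences", {
  set.seed(5)
  ns <- asNamespace("paraseg")
  S <- matrix(rnorm(4 * 30), 4, 30)
  lab <- sample(0:3, 30, replace = TRUE)
  r <- ns$cpp_dice_ce(S, lab, 1e-5)
  h <- 1e-3
  idx <- cbind(sample(4, 12, TRUE), sample(30, 12, TRUE))
  for (k in seq_len(nrow(idx))) {
    S1 <- S; S1[idx[k, 1], idx[k, 2]] <- S1[idx[k, 1], idx[k, 2]] + h
    S2 <- S; S2[idx[k, 1], idx[k, 2]] <- S2[idx[k, 1], idx[k, 2]] - h
    num <- (ns$cpp_dice_ce(S1, lab, 1e-5)$loss - ns$cpp_dice_ce(S2, lab, 1e-5)$loss) / (2 * h)
    # single-precision forward passes bound the finite-difference accuracy
    expect_lt(abs(r$grad[idx[k, 1], idx[k, 2]] - num), 5e-4)
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  pairs <- test_cohort(2)
  ucfg <- unet_config(dims = 2, channels = c(4, 8), seed = 0)
  tcfg <- train_config(dims = 2, iterations = 60, window = c(32, 32, 1),
                       batch_size = 4, num_samples = 2, seed = 0, log_every = 10)
  ck <- train_model(pairs, ucfg, tcfg)
  ll <- ck$loss_log
  expect_lt(tail(ll$loss, 1), head(ll$loss, 1))
  ck2 <- train_model(pairs, ucfg, tcfg)
  expect_identical(ck$params, ck2$params)
  expect_identical(ck$loss_log, ck2$loss_log)
})

test_that("a 3D model trains and predicts with sliding windows", {
  pairs <- test_cohort(2)
  ucfg <- unet_config(dims = 3, channels = c(4, 8), seed = 0)
  tcfg <- train_config(dims = 3, iterations = 40, window = c(32, 32, 8),
                       batch_size = 2, num_samples = 1, seed = 0, log_every = 10)
  ck <- train_model(pairs, ucfg, tcfg)
  expect_lt(tail(ck$loss_log$loss, 1), head(ck$loss_log$loss, 1))
  pred <- predict_volume(ck, pairs[[1]]$image)
  expect_identical(dim(pred$data), dim(pairs[[1]]$image$data))
  expect_true(all(pred$data %in% 0:6))
})

test_that("an overfit 2D model segments its training phantom accurately", {
  pairs <- test_cohort(2)
  ucfg <- unet_config(dims = 2, channels = c(8, 16, 32), seed = 0)
  tcfg <- train_config(dims = 2, iterations = 400, window = c(64, 64, 1),
                       batch_size = 8, num_samples = 4, seed = 0, log_every = 50)
  ck <- train_model(pairs, ucfg, tcfg)
  pred <- predict_volume(ck, pairs[[1]]$image)
  m <- compute_metrics(pred, pairs[[1]]$mask)
  expect_gte(mean(m$dice), 0.95)
  # prediction keeps the geometry contract
  expect_identical(dim(pred$data), dim(pairs[[1]]$mask$data))
})

test_that("predict_volume handles padding and degenerate outputs", {
  m <- build_unet(unet_config(dims = 2, channels = c(4, 8), seed = 0))
  m$train_cfg <- train_config(dims = 2, iterations = 1, window = c(32, 32, 1),
                              batch_size = 1, num_samples = 1)
  # a volume whose extents need padding to the divisibility unit
  img <- image_volume(array(runif(30 * 34 * 3), c(30, 34, 3)), c(1, 1, 5))
  pred <- predict_volume(m, img)
  expect_identical(dim(pred$data), c(30L, 34L, 3L))
  # an all-background prediction is a valid mask of zeros
  zero <- m
  i <- which(zero$layout$block == "final_b")
  off <- zero$layout$offset[i]
  zero$params[off] <- 1e6   # huge background bias forces label 0 everywhere
  pred0 <- predict_volume(zero, img)
  expect_true(all(pred0$data == 0L))
})
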