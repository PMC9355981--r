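ns <- asNamespace("paraseg")

tiny_cfg <- function(...) unet_config(dims = 2, in_channels = 1, out_channels = 4,
                                      channels = c(4, 8), seed = 1, ...)

test_that("convolutions match a direct-loop reference implementation", {
  set.seed(10)
  for (case in list(list(dims = 2, nd = c(6, 5, 1), cin = 2, cout = 3, stride = 1),
                    list(dims = 2, nd = c(8, 6, 1), cin = 3, cout = 2, stride = 2),
                    list(dims = 3, nd = c(6, 6, 4), cin = 2, cout = 2, stride = 1),
                    list(dims = 3, nd = c(8, 6, 4), cin = 1, cout = 3, stride = 2))) {
    x <- array(rnorm(prod(case$nd) * case$cin), c(case$nd, case$cin))
    kz <- if (case$dims == 3) 3 else 1
    w <- array(rnorm(9 * kz * case$cin * case$cout), c(3, 3, kz, case$cin, case$cout))
    b <- rnorm(case$cout)
    got <- ns$cpp_conv3d(x, ref_flatten_w(w, case$dims), b, case$stride, case$dims)
    want <- ref_conv3d(x, w, b, case$stride, case$dims)
    expect_equal(got, want, tolerance = 1e-5)
  }
})

test_that("transpose convolution is the exact adjoint of the strided convolution", {
  set.seed(11)
  nd <- c(3, 3, 1); cin <- 2; cout <- 3
  # adjoint conv maps cout-space (big) -> cin-space (small)
  w <- array(rnorm(9 * cout * cin), c(3, 3, 1, cout, cin))
  b <- rnorm(cout)
  x <- array(rnorm(prod(nd) * cin), c(nd, cin))
  wt <- ref_flatten_w(w, 2)           # (cin, cout*K)
  got <- ns$cpp_tconv3d(x, wt, b, 2)
  want <- ref_tconv_dense(x, w, b, 2) # dense-matrix transpose oracle
  expect_equal(got, want, tolerance = 1e-5)
  expect_identical(dim(got), c(6L, 6L, 1L, 3L))
})

test_that("instance normalisation standardises each feature map", {
  set.seed(12)
  x <- matrix(rnorm(5 * 400, mean = 3, sd = 2), 5, 400)
  y <- ns$cpp_instance_norm(x, gamma = rep(1, 5), beta = rep(0, 5), eps = 1e-5)
  expect_equal(rowMeans(y), rep(0, 5), tolerance = 1e-5)
  expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 5), tolerance = 1e-3)
  # affine parameters shift and scale the normalised maps
  y2 <- ns$cpp_instance_norm(x, gamma = rep(2, 5), beta = rep(1, 5), eps = 1e-5)
  expect_equal(y2, 2 * y + 1, tolerance = 1e-5)
})

test_that("output shape equals input shape for 2D and 3D windows", {
  m2 <- build_unet(unet_config(dims = 2, seed = 0))
  s2 <- unet_forward(m2, array(rnorm(256 * 256), c(256, 256)))
  expect_identical(dim(s2), c(256L, 256L, 1L, 7L, 1L))
  expect_true(all(is.finite(s2)))
  m3 <- build_unet(unet_config(dims = 3, seed = 0))
  s3 <- unet_forward(m3, array(rnorm(64 * 64 * 32), c(64, 64, 32)))
  expect_identical(dim(s3), c(64L, 64L, 32L, 7L, 1L))
  expect_true(all(is.finite(s3)))
})

test_that("forward pass is deterministic and rejects non-divisible windows", {
  m <- build_unet(tiny_cfg())
  x <- array(rnorm(32 * 32), c(32, 32))
  expect_identical(unet_forward(m, x), unet_forward(m, x))
  expect_error(unet_forward(m, array(0, c(31, 32))), "divisible")
  expect_error(unet_forward(m, array(0, c(32, 31))), "y extent")
})

test_that("parameter counting is exact and monotone", {
  # hand count: a 1x1 convolution from 1 channel to 7 with bias has 14 scalars
  m <- build_unet(unet_config(dims = 2, channels = c(1, 2), out_channels = 7,
                              in_channels = 1, seed = 0))
  lay <- m$layout
  expect_equal(lay$length[lay$block == "final_W"] + lay$length[lay$block == "final_b"],
               14)
  expect_equal(count_parameters(m), sum(lay$length))

  base <- build_unet(unet_config(dims = 2, seed = 0))
  deep <- build_unet(unet_config(dims = 2, deeper = TRUE, seed = 0))
  expect_gt(count_parameters(deep), count_parameters(base))
  expect_equal(max(deep$cfg$channels), 512)

  # 3D kernels are 3x larger per conv: parameter count strictly larger
  b3 <- build_unet(unet_config(dims = 3, seed = 0))
  expect_gt(count_parameters(b3), count_parameters(base))

  # doubling all channel widths roughly quadruples conv-dominated counts
  wide <- build_unet(unet_config(dims = 2, channels = 2 * c(16, 32, 64, 128, 256),
                                 seed = 0))
  big <- build_unet(unet_config(dims = 2, channels = c(16, 32, 64, 128, 256),
                                seed = 0))
  expect_gt(count_parameters(wide) / count_parameters(big), 3.5)
  expect_lt(count_parameters(wide) / count_parameters(big), 4.3)
})

test_that("zero-weight residual stages act as the (projected) identity", {
  cfg <- tiny_cfg()
  m <- build_unet(cfg)
  lay <- m$layout
  # zero every conv weight/bias and norm shift of encoder level 1's stage
  p <- m$params
  for (blk in c("enc1_res1_W", "enc1_res1_b", "enc1_res1_be",
                "enc1_res2_W", "enc1_res2_b", "enc1_res2_be")) {
    i <- which(lay$block == blk)
    p[seq(lay$offset[i], length.out = lay$length[i])] <- 0
  }
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  act <- ns$cpp_unet_activations(ns$cfg_for_cpp(cfg), p, x)
  # the stage output equals its input (the down block's activation) exactly
  expect_equal(act$enc1_res, act$enc1_down, tolerance = 1e-6)
  # with the original (nonzero) weights the stage is not the identity
  act0 <- ns$cpp_unet_activations(ns$cfg_for_cpp(cfg), m$params, x)
  expect_gt(max(abs(act0$enc1_res - act0$enc1_down)), 1e-3)
})

test_that("the network is shift-equivariant on interior content", {
  # content far from borders, shifted by the downsampling factor, produces a
  # correspondingly shifted score map on the interior
  # the content and its receptive-field cone must stay away from the volume
  # border in both positions, so the grid is generous around a small blob
  cfg <- tiny_cfg()
  m <- build_unet(cfg)
  n <- 64; shift <- 2   # 2 levels -> downsampling/shift unit 2
  set.seed(13)
  blob <- array(rnorm(8 * 8), c(8, 8))
  x1 <- array(0, c(n, n)); x1[25:32, 25:32] <- blob
  x2 <- array(0, c(n, n)); x2[(25 + shift):(32 + shift), 25:32] <- blob
  s1 <- unet_forward(m, x1)[, , 1, , 1]
  s2 <- unet_forward(m, x2)[, , 1, , 1]
  a <- s1[17:44, 17:44, ]
  b <- s2[(17 + shift):(44 + shift), 17:44, ]
  expect_equal(a, b, tolerance = 1e-4)
})

test_that("weight initialisation is seeded and reproducible", {
  a <- build_unet(tiny_cfg())
  b <- build_unet(tiny_cfg())
  expect_identical(a$params, b$params)
  c2 <- build_unet(unet_config(dims = 2, in_channels = 1, out_channels = 4,
                               channels = c(4, 8), seed = 2))
  expect_false(identical(a$params, c2$params))
})

test_that("checkpoints round-trip through disk", {
  td <- withr::local_tempdir()
  m <- build_unet(tiny_cfg())
  save_checkpoint(m, file.path(td, "m.rds"))
  m2 <- load_checkpoint(file.path(td, "m.rds"))
  expect_identical(m2$params, m$params)
  expect_identical(m2$cfg$channels, m$cfg$channels)
})
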