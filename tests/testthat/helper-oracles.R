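# Independent reference implementations used as oracles. These are written
# as plain, slow, loop-based R so that they share no code path with the
# package's engine.

# direct-loop 3D convolution, kernel 3 (z extent 1 in 2D mode), zero pad 1.
# w indexed [kx, ky, kz, cin, cout] with offsets -1..1 (z offset 0 in 2D).
ref_conv3d <- function(x, w, bias, stride = 1, dims = 2) {
  nd <- dim(x)
  cin <- nd[4]
  cout <- dim(w)[5]
  kz <- if (dims == 3) -1:1 else 0
  stz <- if (dims == 3) stride else 1
  out_n <- c(floor((nd[1] - 1) / stride) + 1, floor((nd[2] - 1) / stride) + 1,
             if (dims == 3) floor((nd[3] - 1) / stride) + 1 else nd[3])
  y <- array(0, c(out_n, cout))
  for (co in seq_len(cout)) for (oz in seq_len(out_n[3])) {
    for (oy in seq_len(out_n[2])) for (ox in seq_len(out_n[1])) {
      acc <- bias[co]
      for (dz in kz) for (dy in -1:1) for (dx in -1:1) {
        ix <- (ox - 1) * stride + dx + 1
        iy <- (oy - 1) * stride + dy + 1
        iz <- (oz - 1) * stz + dz + 1
        if (ix >= 1 && ix <= nd[1] && iy >= 1 && iy <= nd[2] &&
            iz >= 1 && iz <= nd[3]) {
          for (ci in seq_len(cin))
            acc <- acc + w[dx + 2, dy + 2, dz + (if (dims == 3) 2 else 1), ci, co] *
              x[ix, iy, iz, ci]
        }
      }
      y[ox, oy, oz, co] <- acc
    }
  }
  y
}

# map a [kx, ky, kz, cin, cout] kernel to the engine's (cout, k*cin + ci)
# flat weight matrix (k = ix + 3*(iy + 3*iz), zero-based offsets)
ref_flatten_w <- function(w, dims = 2) {
  kzn <- if (dims == 3) 3 else 1
  cin <- dim(w)[4]; cout <- dim(w)[5]
  W <- matrix(0, cout, 9 * kzn * cin)
  for (iz in seq_len(kzn)) for (iy in 1:3) for (ix in 1:3) {
    k <- (ix - 1) + 3 * ((iy - 1) + 3 * (iz - 1))
    for (ci in seq_len(cin))
      W[, k * cin + ci] <- w[ix, iy, iz, ci, ]
  }
  W
}

# dense-matrix adjoint: build the stride-2 conv as an explicit matrix on a
# tiny grid, then apply its transpose (the definition of transpose conv)
ref_tconv_dense <- function(x, w, bias, dims = 2) {
  nd <- dim(x)
  cin <- dim(w)[4]   # adjoint conv maps cout-space -> cin-space
  cout <- dim(w)[5]
  stopifnot(nd[4] == cout)
  big_n <- c(nd[1] * 2, nd[2] * 2, if (dims == 3) nd[3] * 2 else nd[3])
  nbig <- prod(big_n) * cin
  nsmall <- prod(nd)
  M <- matrix(0, nsmall, nbig)
  for (j in seq_len(nbig)) {
    e <- array(0, c(big_n, cin)); e[j] <- 1
    M[, j] <- as.vector(ref_conv3d(e, w, rep(0, cout), stride = 2, dims = dims))
  }
  y <- as.vector(t(M) %*% as.vector(x))
  y <- array(y, c(big_n, cin))
  for (ci in seq_len(cin)) y[, , , ci] <- y[, , , ci] + bias[ci]
  y
}

# brute-force per-voxel confusion counts
ref_confusion <- function(pred, gt, label) {
  tp <- fp <- fn <- tn <- 0
  for (v in seq_along(pred)) {
    p <- pred[v] == label; g <- gt[v] == label
    if (p && g) tp <- tp + 1 else if (p) fp <- fp + 1
    else if (g) fn <- fn + 1 else tn <- tn + 1
  }
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

ref_metrics <- function(pred, gt) {
  cc <- as.list(ref_confusion(pred, gt, 1))
  sm <- cc$TP + cc$FP; g <- cc$TP + cc$FN
  list(dice = 2 * cc$TP / (sm + g),
       jaccard = cc$TP / (sm + g - cc$TP),
       conformity = 1 - (cc$FP + cc$FN) / cc$TP,
       tpr = cc$TP / g,
       tnr = cc$TN / (cc$TN + cc$FP),
       ppv = cc$TP / sm,
       volume_ratio = sm / g)
}

# 6-connected components of a binary 3D array (breadth-first flood fill)
n_components6 <- function(bin) {
  nd <- dim(bin)
  lab <- array(0L, nd)
  nxt <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  idx <- which(bin)
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      v0 <- v - 1L
      co <- c(v0 %% nd[1], (v0 %/% nd[1]) %% nd[2], v0 %/% (nd[1] * nd[2])) + 1L
      for (k in 1:6) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > nd)) next
        w <- nb[1] + nd[1] * (nb[2] - 1) + nd[1] * nd[2] * (nb[3] - 1)
        if (bin[w] && lab[w] == 0L) { lab[w] <- nxt; queue <- c(queue, w) }
      }
    }
  }
  nxt
}

# ICC(2,1) point estimate from an explicit two-way aov() decomposition
ref_icc21_aov <- function(x, y) {
  n <- length(x)
  df <- data.frame(score = c(x, y),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# small deterministic phantom cohort shared across tests (built once)
test_cohort <- local({
  cache <- NULL
  function(n = 2, noiseless = TRUE) {
    key <- paste(n, noiseless)
    if (!is.null(cache) && identical(attr(cache, "key"), key)) return(cache)
    cfg <- if (noiseless)
      phantom_config(fat_fraction_range = c(0, 0), bias_amplitude = 0, noise_sd = 0)
    else phantom_config()
    out <- lapply(seq_len(n), function(i) generate_phantom(cfg, i))
    attr(out, "key") <- key
    cache <<- out
    out
  }
})

with_seed_local <- function(seed, expr) { set.seed(seed); expr }
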