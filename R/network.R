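#' Configuration of the modified U-Net
#'
#' The architecture is a U-Net in which max-pooling is replaced by stride-2
#' convolutions for downsampling (stride 1 at the first level), upsampling
#' uses stride-2 transpose convolutions, encoder feature maps are
#' concatenated to the decoder via skip connections, and each resolution
#' level carries a residual stage: two (conv 3x3(x3) -> instance norm ->
#' leaky ReLU) units whose input is added to their output (with a 1x1
#' projection on the shortcut when channel counts differ, as after a skip
#' concatenation). A final 1x1 convolution maps to per-class scores.
#'
#' @param dims 2 or 3 (2D networks operate on squeezed single slices).
#' @param in_channels Input channels (default 1).
#' @param out_channels Output classes (default 7: background + six muscles).
#' @param channels Filters per resolution level, strictly increasing
#'   (default `c(16, 32, 64, 128, 256)`).
#' @param deeper Append one extra level with twice the top filter count
#'   (512 with the default channels), adding depth rather than width.
#' @param slope Negative slope of the leaky ReLU (default 0.01).
#' @param eps Instance-normalisation epsilon (default 1e-5).
#' @param seed Seed for weight initialisation.
#' @return A `unet_config` list.
#' @export
unet_config <- function(dims = 2, in_channels = 1, out_channels = 7,
                        channels = c(16, 32, 64, 128, 256), deeper = FALSE,
                        slope = 0.01, eps = 1e-5, seed = 0L) {
  if (isTRUE(deeper)) channels <- c(channels, 2 * channels[length(channels)])
  channels <- as.integer(channels)
  if (length(channels) < 2) stopf("at least two resolution levels are required")
  if (any(diff(channels) <= 0)) stopf("channels must be strictly increasing")
  if (out_channels < 2) stopf("out_channels must be >= 2")
  if (!dims %in% c(2, 3)) stopf("dims must be 2 or 3")
  structure(list(dims = as.integer(dims), in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels), channels = channels,
                 deeper = isTRUE(deeper), slope = slope, eps = eps,
                 seed = as.integer(seed)),
            class = "unet_config")
}

cfg_for_cpp <- function(cfg) {
  list(dims = cfg$dims, in_channels = cfg$in_channels,
       out_channels = cfg$out_channels, channels = cfg$channels,
       slope = cfg$slope, eps = cfg$eps)
}

#' Build a modified U-Net model
#'
#' Instantiates the parameter vector for a [unet_config()]: convolution
#' weights use He initialisation adjusted for the leaky ReLU slope,
#' instance-norm gains start at 1, and all biases and shifts at 0.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [unet_config()].
#' @return A `unet_model`: list with `cfg`, the flat `params` vector, and the
#'   parameter `layout` table (block name, shape, offset, fan-in).
#' @export
build_unet <- function(cfg) {
  stopifnot(inherits(cfg, "unet_config"))
  layout <- cpp_unet_layout(cfg_for_cpp(cfg))
  total <- sum(layout$length)
  params <- numeric(total)
  with_seed(cfg$seed, {
    for (i in seq_len(nrow(layout))) {
      idx <- seq(layout$offset[i], length.out = layout$length[i])
      if (grepl("_W$", layout$block[i])) {
        sdv <- sqrt(2 / ((1 + cfg$slope^2) * layout$fan_in[i]))
        params[idx] <- stats::rnorm(layout$length[i], 0, sdv)
      } else if (grepl("_g$", layout$block[i])) {
        params[idx] <- 1
      }  # biases and shifts stay 0
    }
  })
  structure(list(cfg = cfg, params = params, layout = layout),
            class = "unet_model")
}

#' Number of trainable parameters
#'
#' @param model A `unet_model` or checkpoint.
#' @return Integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  length(model$params)
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("<unet_model> %dD, channels %s, %s parameters\n", x$cfg$dims,
              paste(x$cfg$channels, collapse = "-"),
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# normalise input arrays to the engine's (nx, ny, nz, channels, batch) layout
as_input5d <- function(x, dims) {
  d <- dim(x)
  if (is.null(d)) stopf("input must be an array")
  if (length(d) == 2) d <- c(d, 1L)
  if (length(d) == 3) d <- c(d, 1L, 1L)
  if (length(d) == 4) d <- c(d, 1L)
  if (length(d) != 5) stopf("input must have 2 to 5 dimensions")
  dim(x) <- d
  storage.mode(x) <- "double"
  x
}

#' Forward evaluation of a U-Net
#'
#' Computes unnormalised per-class score maps. Spatial extents must be
#' divisible by `2^(levels - 1)`; 2D models take single-slice input
#' (the unitary third dimension is squeezed internally).
#'
#' @param model A `unet_model` (or checkpoint with `cfg` and `params`).
#' @param x Input array: `(nx, ny)` or `(nx, ny, nz)` for one sample, or the
#'   full `(nx, ny, nz, channels, batch)` layout.
#' @return Array `(nx, ny, nz, out_channels, batch)` of class scores.
#' @export
unet_forward <- function(model, x) {
  x <- as_input5d(x, model$cfg$dims)
  cpp_unet_forward(cfg_for_cpp(model$cfg), model$params, x)
}

#' Save or load a self-describing checkpoint
#'
#' A checkpoint bundles the weights with the network and training
#' configurations, so it can be reloaded without external context.
#'
#' @param model A `unet_model` or trained checkpoint.
#' @param path File path.
#' @return `path` (write) or the restored object (read).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (is.null(m$cfg) || is.null(m$params)) stopf("not a valid checkpoint: %s", path)
  m
}
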