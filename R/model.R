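#' CNN architecture configuration
#'
#' The fixed sequential architecture: `n_conv_blocks` blocks of (3 x 3
#' convolution, padding 1) -> ReLU -> (2 x 2 max pool). The first block
#' maps the 3 input phases to `base_feature_maps` channels and every later
#' block doubles the channel count, so with the defaults the sixth block
#' emits 512 feature maps on a 1 x 1 grid after its pool; a 512 -> 256
#' linear layer with ReLU and a 256 -> 1 linear layer with a sigmoid close
#' the network. The spatial size must collapse exactly to 1 x 1
#' (`input_size == pool^n_conv_blocks`).
#'
#' @param in_channels number of input channels (dynamic phases).
#' @param input_size square input side length in pixels.
#' @param base_feature_maps channels emitted by the first block.
#' @param n_conv_blocks number of conv/ReLU/pool blocks.
#' @param fc_hidden width of the first fully connected layer.
#' @param kernel,padding,pool convolution kernel size, padding and pooling
#'   factor; only 3/1/2 are supported.
#' @return Object of class `model_config`.
#' @export
model_config <- function(in_channels = 3L, input_size = 64L,
                         base_feature_maps = 16L, n_conv_blocks = 6L,
                         fc_hidden = 256L, kernel = 3L, padding = 1L,
                         pool = 2L) {
  if (kernel != 3L || padding != 1L || pool != 2L)
    stop("only 3x3 kernels with padding 1 and 2x2 pooling are supported",
         call. = FALSE)
  if (input_size != pool^n_conv_blocks)
    stop("pooling must reduce the input exactly to 1x1: input_size ",
         input_size, " != ", pool, "^", n_conv_blocks, call. = FALSE)
  structure(
    list(in_channels = as.integer(in_channels),
         input_size = as.integer(input_size),
         base_feature_maps = as.integer(base_feature_maps),
         n_conv_blocks = as.integer(n_conv_blocks),
         fc_hidden = as.integer(fc_hidden),
         kernel = 3L, padding = 1L, pool = 2L),
    class = "model_config"
  )
}

# channel widths entering/leaving each conv block
config_channels <- function(config) {
  outs <- config$base_feature_maps * 2^(seq_len(config$n_conv_blocks) - 1L)
  list(ins = c(config$in_channels, outs[-config$n_conv_blocks]), outs = outs)
}

he_uniform <- function(nr, nc) {
  lim <- sqrt(6 / nc)
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Build a grade-classification CNN
#'
#' Instantiates the architecture of [model_config()] with He-uniform weight
#' initialisation (bound `sqrt(6 / fan_in)`) and zero biases; given the same
#' seed the initial weights are identical.
#'
#' @param config a [model_config()].
#' @param seed integer seed for the weight draw.
#' @return Object of class `grade_cnn`: list with `config`, `weights`,
#'   `seed`, `n_parameters`.
#' @export
build_grade_cnn <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  set.seed(seed)
  ch <- config_channels(config)
  conv <- lapply(seq_len(config$n_conv_blocks), function(b) {
    list(W = he_uniform(ch$outs[b], ch$ins[b] * 9L),
         b = rep(0, ch$outs[b]))
  })
  flat_dim <- ch$outs[config$n_conv_blocks]
  weights <- list(
    conv = conv,
    fc1 = list(W = he_uniform(config$fc_hidden, flat_dim),
               b = rep(0, config$fc_hidden)),
    fc2 = list(W = he_uniform(1L, config$fc_hidden), b = 0)
  )
  model <- structure(
    list(config = config, weights = weights, seed = as.integer(seed)),
    class = "grade_cnn"
  )
  model$n_parameters <- n_parameters(model)
  model
}

#' Total trainable parameter count
#'
#' @param model a `grade_cnn`.
#' @return Integer number of weights and biases.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "grade_cnn"))
  sum(unlist(weight_map(length, model$weights)))
}

#' Layer-by-layer summary of the architecture
#'
#' Shape introspection of the built network: channels and spatial size
#' entering and leaving each conv block, then the fully connected head.
#'
#' @param model a `grade_cnn`.
#' @return Tibble with columns `layer`, `in_channels`, `out_channels`,
#'   `spatial_in`, `spatial_out`.
#' @export
model_summary <- function(model) {
  stopifnot(inherits(model, "grade_cnn"))
  cfg <- model$config
  ch <- config_channels(cfg)
  sizes <- cfg$input_size / 2^(0:cfg$n_conv_blocks)
  conv_rows <- tibble(
    layer = paste0("conv_block_", seq_len(cfg$n_conv_blocks)),
    in_channels = ch$ins,
    out_channels = ch$outs,
    spatial_in = as.integer(sizes[-length(sizes)]),
    spatial_out = as.integer(sizes[-1])
  )
  dplyr::bind_rows(
    conv_rows,
    tibble(layer = c("fc1", "fc2"),
           in_channels = c(nrow(model$weights$fc1$W) * 0L +
                             ncol(model$weights$fc1$W),
                           ncol(model$weights$fc2$W)),
           out_channels = c(nrow(model$weights$fc1$W),
                            nrow(model$weights$fc2$W)),
           spatial_in = 1L, spatial_out = 1L)
  )
}

#' @export
print.grade_cnn <- function(x, ...) {
  cat("<grade_cnn>", x$config$n_conv_blocks, "conv blocks,",
      x$config$base_feature_maps, "->",
      x$config$base_feature_maps * 2^(x$config$n_conv_blocks - 1),
      "channels,", format(x$n_parameters, big.mark = ","), "parameters\n")
  invisible(x)
}

# elementwise map over parallel nested weight structures
weight_map <- function(f, ...) {
  ws <- list(...)
  if (is.list(ws[[1]])) {
    out <- lapply(seq_along(ws[[1]]), function(i) {
      do.call(weight_map, c(list(f), lapply(ws, `[[`, i)))
    })
    names(out) <- names(ws[[1]])
    out
  } else {
    do.call(f, ws)
  }
}

# config fields the C++ kernels need
cpp_config <- function(config) {
  config[c("in_channels", "base_feature_maps", "n_conv_blocks", "input_size")]
}

#' Forward pass: per-slice malignancy-grade probabilities
#'
#' Runs the network on one or more slice samples and returns the sigmoid
#' output, a probability strictly inside (0, 1) that the slice looks
#' NHG3-like.
#'
#' @param object a `grade_cnn`.
#' @param newdata a `slice_sample`, a list of them, or a (64, 64, 3, N)
#'   array.
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict.grade_cnn <- function(object, newdata, ...) {
  x <- if (is.array(newdata) && length(dim(newdata)) == 4L) newdata
       else slice_batch(newdata)
  .cnn_forward(object$weights, cpp_config(object$config), x)
}

#' Grad-CAM saliency map
#'
#' Gradient-weighted class activation mapping at one conv block: channel
#' weights are the spatial means of the logit gradient with respect to the
#' block's post-ReLU activations, the weighted activation sum is rectified,
#' bilinearly upsampled to the input resolution, and max-normalised to 1
#' when non-zero. The default target is the final (sixth) conv block, whose
#' 2 x 2 pre-pool activation grid is the deepest layer with any spatial
#' extent.
#'
#' @param model a `grade_cnn`.
#' @param sample a `slice_sample` (or bare 3 x 64 x 64 array).
#' @param target_block conv block index in 1..`n_conv_blocks`.
#' @return Object of class `grad_cam_map`: list with `heatmap` (64 x 64,
#'   values in \[0, 1\]), `raw` (pre-normalisation map at native
#'   resolution), `target_block`, `prob`, `patient_id`.
#' @export
grad_cam <- function(model, sample, target_block = 6L) {
  stopifnot(inherits(model, "grade_cnn"))
  x <- if (inherits(sample, "slice_sample")) aperm(sample$x, c(2, 3, 1))
       else sample
  stopifnot(length(dim(x)) == 3L)
  res <- .cnn_cam_grad(model$weights, cpp_config(model$config), x,
                       as.integer(target_block))
  side <- res$side
  if (side == 1L)
    warning("target block has 1x1 spatial extent; the heatmap is spatially uninformative",
            call. = FALSE)
  alpha <- rowMeans(res$gradient)
  cam <- colSums(res$activation * alpha)       # sum_c alpha_c A_c per pixel
  cam <- pmax(matrix(cam, side, side), 0)
  up <- bilinear_resize(cam, model$config$input_size)
  m <- max(up)
  heat <- if (m > 0) up / m else up
  structure(
    list(heatmap = heat, raw = cam, target_block = as.integer(target_block),
         prob = res$prob,
         patient_id = if (inherits(sample, "slice_sample"))
           sample$patient_id else NA_character_),
    class = "grad_cam_map"
  )
}

# bilinear upsampling on the pixel-centre grid (align_corners = FALSE)
bilinear_resize <- function(m, out_side) {
  side <- nrow(m)
  if (side == out_side) return(m)
  pos <- (seq_len(out_side) - 0.5) / out_side * side - 0.5
  lo <- clip(floor(pos), 0, side - 1)
  hi <- clip(lo + 1, 0, side - 1)
  w <- clip(pos - lo, 0, 1)
  i0 <- lo + 1; i1 <- hi + 1
  a <- m[i0, i0, drop = FALSE] * outer(1 - w, 1 - w) +
    m[i1, i0, drop = FALSE] * outer(w, 1 - w) +
    m[i0, i1, drop = FALSE] * outer(1 - w, w) +
    m[i1, i1, drop = FALSE] * outer(w, w)
  a
}
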