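# Composable tensor operators: 3-D depthwise-separable convolution, the
# channel-expansion convolution (CEC) unit, and the inverted residual block.

abort_contract <- function(msg) {
  rlang::abort(msg, class = "munet3d_contract_error")
}

#' Describe the shape of a dense 4-D feature array
#'
#' A `tensor_shape` records the channel count and the depth/height/width voxel
#' extents of a feature map, the bookkeeping unit used by the analytic
#' complexity engine.
#'
#' @param channels,depth,height,width Positive integer extents.
#' @return A `tensor_shape` object (named list).
#' @export
#' @examples
#' tensor_shape(16, 8, 8, 8)
tensor_shape <- function(channels, depth, height, width) {
  ext <- c(channels = channels, depth = depth, height = height, width = width)
  if (any(ext < 1) || any(ext != as.integer(ext))) {
    abort_contract("all tensor_shape extents must be positive integers")
  }
  ext <- as.integer(ext)
  structure(list(channels = ext[1L], depth = ext[2L], height = ext[3L], width = ext[4L]),
            class = "tensor_shape")
}

#' @export
format.tensor_shape <- function(x, ...) {
  sprintf("<tensor_shape %d x %d x %d x %d (C x D x H x W)>",
          x$channels, x$depth, x$height, x$width)
}

#' @export
print.tensor_shape <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Specify a single 3-D convolution layer
#'
#' A `conv_spec` fully describes one convolution layer for the purpose of
#' analytic parameter/FLOP accounting and of instantiating weights: its kind
#' (standard, depthwise, pointwise, separable, or transpose), channel counts,
#' kernel and stride.  A separable layer is exactly one depthwise stage
#' followed by one pointwise stage.
#'
#' @param kind One of `"standard"`, `"depthwise"`, `"pointwise"`,
#'   `"separable"`, `"transpose"`.
#' @param in_channels,out_channels Positive integer channel counts.  A
#'   depthwise layer requires `out_channels == in_channels`.
#' @param kernel Integer triple `(K_D, K_H, K_W)`.  A pointwise layer requires
#'   `c(1, 1, 1)`.
#' @param stride Integer triple; defaults to unit stride.
#' @param has_bias Logical; the network convolutions carry no biases, which
#'   keeps the analytic parameter count equal to the kernel-weight count.
#' @return A `conv_spec` object.
#' @export
#' @examples
#' conv_spec("separable", 16, 32)
conv_spec <- function(kind, in_channels, out_channels,
                      kernel = c(3L, 3L, 3L), stride = c(1L, 1L, 1L),
                      has_bias = FALSE) {
  kind <- match.arg(kind, c("standard", "depthwise", "pointwise", "separable", "transpose"))
  kernel <- as.integer(rep(kernel, length.out = 3L))
  stride <- as.integer(rep(stride, length.out = 3L))
  if (in_channels < 1 || out_channels < 1) {
    abort_contract("channel counts must be positive")
  }
  if (any(kernel < 1) || any(stride < 1)) {
    abort_contract("kernel and stride extents must be positive")
  }
  if (kind == "depthwise" && out_channels != in_channels) {
    abort_contract("a depthwise convolution preserves its channel count")
  }
  if (kind == "pointwise" && any(kernel != 1L)) {
    abort_contract("a pointwise convolution has kernel 1x1x1")
  }
  structure(list(kind = kind, in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels), kernel = kernel,
                 stride = stride, has_bias = isTRUE(has_bias)),
            class = "conv_spec")
}

#' Specify a channel-expansion convolution (CEC) unit
#'
#' The CEC unit widens its input from `in_channels` to
#' `expansion_factor * in_channels` with a 1x1x1 convolution, applies a
#' depthwise 3x3x3 convolution in the widened space, and compresses back to
#' `out_channels` with a second 1x1x1 convolution.  The expansion and
#' depthwise stages each end in a leaky-rectified activation followed by
#' per-instance channel normalization; the compression stage is linear so the
#' narrow representation is not clipped.  With `use_residual` the unit becomes
#' an inverted residual block; the identity skip is only admissible when input
#' and output channel counts match (and stride is 1, which all units here
#' are).
#'
#' @param in_channels,out_channels Positive integers.
#' @param expansion_factor Positive integer `t`; internal width is
#'   `t * in_channels`.
#' @param depthwise_kernel Odd integer triple, default 3x3x3.
#' @param negative_slope Slope of the leaky activation for negative inputs.
#' @param use_residual Add the input to the output (requires matching channel
#'   counts).
#' @return A `cec_spec` object.
#' @export
#' @examples
#' cec_spec(16, 24, expansion_factor = 6)
cec_spec <- function(in_channels, out_channels, expansion_factor,
                     depthwise_kernel = c(3L, 3L, 3L),
                     negative_slope = 0.01, use_residual = FALSE) {
  if (expansion_factor < 1 || expansion_factor != as.integer(expansion_factor)) {
    abort_contract("expansion_factor t must be a positive integer")
  }
  if (in_channels < 1 || out_channels < 1) {
    abort_contract("channel counts must be positive")
  }
  if (isTRUE(use_residual) && in_channels != out_channels) {
    abort_contract("a residual connection requires in_channels == out_channels")
  }
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 expansion_factor = as.integer(expansion_factor),
                 depthwise_kernel = as.integer(rep(depthwise_kernel, length.out = 3L)),
                 negative_slope = negative_slope,
                 use_residual = isTRUE(use_residual)),
            class = "cec_spec")
}

check_input_channels <- function(x, expected) {
  d <- dim(x)
  if (length(d) != 4L) abort_contract("feature array must be 4-D (C x D x H x W)")
  if (d[1L] != expected) {
    abort_contract(sprintf("input has %d channels but the spec expects %d", d[1L], expected))
  }
  invisible(d)
}

#' Apply a 3-D depthwise convolution
#'
#' Convolution is performed independently on each input channel: output
#' channel `c` depends only on input channel `c`.  Stride 1, "same" padding,
#' so spatial extents are preserved.
#'
#' @param x Numeric 4-D array `(C, D, H, W)`.
#' @param spec A [conv_spec()] with `kind = "depthwise"`.
#' @param weights Array `(C, K_D, K_H, K_W)`: one kernel per channel.
#' @return A 4-D array with the same dimensions as `x`.
#' @export
apply_depthwise_conv3d <- function(x, spec, weights) {
  if (spec$kind != "depthwise") abort_contract("spec$kind must be 'depthwise'")
  d <- check_input_channels(x, spec$in_channels)
  if (!identical(dim(weights), c(spec$in_channels, spec$kernel))) {
    abort_contract("weights must hold in_channels kernels of size K_D x K_H x K_W")
  }
  if (any(spec$kernel > d[-1L] + (spec$kernel - 1L))) {
    abort_contract("kernel larger than the padded input")
  }
  conv3d_depthwise_fwd(x, weights)
}

#' Apply a 3-D pointwise (1x1x1) convolution
#'
#' Every output voxel is a linear combination of the input channels at the
#' same spatial position; spatial extents are unchanged.
#'
#' @param x Numeric 4-D array `(C, D, H, W)`.
#' @param spec A [conv_spec()] with `kind = "pointwise"`.
#' @param weights Matrix `(out_channels, in_channels)`.
#' @return A 4-D array `(out_channels, D, H, W)`.
#' @export
apply_pointwise_conv3d <- function(x, spec, weights) {
  if (spec$kind != "pointwise") abort_contract("spec$kind must be 'pointwise'")
  check_input_channels(x, spec$in_channels)
  if (!identical(dim(weights), c(spec$out_channels, spec$in_channels))) {
    abort_contract("weights must be an out_channels x in_channels mixing matrix")
  }
  conv3d_pointwise_fwd(x, weights)
}

#' Initialize the weights of a CEC unit
#'
#' Fan-in-scaled uniform initialization (He-style bound `sqrt(3 / fan_in)`)
#' for the three convolution stages; normalization gains start at 1 and
#' offsets at 0.
#'
#' @param spec A [cec_spec()].
#' @param rng_seed Optional integer seed for reproducible draws.
#' @return A named list of weight arrays understood by [apply_cec_unit()].
#' @export
cec_init_weights <- function(spec, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ce <- spec$in_channels * spec$expansion_factor
  kd <- spec$depthwise_kernel
  runif_arr <- function(dims, fan_in) {
    b <- sqrt(3 / fan_in)
    array(stats::runif(prod(dims), -b, b), dims)
  }
  list(
    expand = runif_arr(c(ce, spec$in_channels), spec$in_channels),
    expand_gamma = rep(1, ce), expand_beta = rep(0, ce),
    dw = runif_arr(c(ce, kd), prod(kd)),
    dw_gamma = rep(1, ce), dw_beta = rep(0, ce),
    compress = runif_arr(c(spec$out_channels, ce), ce)
  )
}

#' Apply a channel-expansion convolution unit
#'
#' Expansion (1x1x1) and depthwise (3x3x3) stages each end with a leaky
#' rectified activation followed by per-instance channel normalization; the
#' compression stage (1x1x1) has a linear activation and no normalization.
#'
#' @param x Numeric 4-D array `(in_channels, D, H, W)`.
#' @param spec A [cec_spec()].
#' @param weights Weight list as produced by [cec_init_weights()].
#' @param normalize Apply instance normalization after the first two stages
#'   (disable to test pure convolution algebra).
#' @return A 4-D array `(out_channels, D, H, W)`.
#' @export
apply_cec_unit <- function(x, spec, weights, normalize = TRUE) {
  check_input_channels(x, spec$in_channels)
  h <- conv3d_pointwise_fwd(x, weights$expand)
  h <- leaky_relu_fwd(h, spec$negative_slope)$y
  if (normalize) h <- instnorm_fwd(h, weights$expand_gamma, weights$expand_beta)$y
  h <- conv3d_depthwise_fwd(h, weights$dw)
  h <- leaky_relu_fwd(h, spec$negative_slope)$y
  if (normalize) h <- instnorm_fwd(h, weights$dw_gamma, weights$dw_beta)$y
  conv3d_pointwise_fwd(h, weights$compress)
}

#' Apply an inverted residual block
#'
#' Runs [apply_cec_unit()] and, when the spec requests a residual connection
#' (admissible only for matching channel counts at stride 1), adds the input
#' feature map elementwise to the output.
#'
#' @inheritParams apply_cec_unit
#' @return A 4-D array `(out_channels, D, H, W)`.
#' @export
apply_inverted_residual <- function(x, spec, weights, normalize = TRUE) {
  y <- apply_cec_unit(x, spec, weights, normalize = normalize)
  if (spec$use_residual) {
    if (dim(x)[1L] != dim(y)[1L]) {
      abort_contract("residual connection requires matching channel counts")
    }
    y <- y + x
  }
  y
}
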