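# Network assembly: the lightweight multi-task mobile 3-D U-Net and the
# classical 3-D U-Net baseline, built from one declarative configuration.
#
# Topology: `num_levels` encoder modules, each two feature-extraction units
# followed by 2x2x2 max pooling; module i outputs base_channels * 2^(i-1)
# channels (the first unit performs the doubling).  The decoder mirrors the
# encoder: per level a 2x2x2 stride-2 transpose convolution doubles extents
# and maps onto that level's width, the encoder skip is concatenated
# (upsampled features first), and two feature-recovery units compress back to
# the level width.  A final 1x1x1 convolution and sigmoid produce per-voxel
# probabilities.  In the mobile variant every unit is a CEC unit wrapped as
# an inverted residual block (the identity skip is active whenever the unit
# preserves its channel count); the baseline variant uses one standard 3x3x3
# convolution + leaky ReLU + instance norm per unit.  The optional auxiliary
# classification head attaches to the deepest encoder features (configurable
# to the decoder end), collapses depth by averaging, applies a 2-D 3x3
# convolution with half the input width, global max pooling, and a linear
# layer to the class count.

#' Declare a network architecture
#'
#' @param variant `"baseline_3dunet"` (standard 3x3x3 convolutions) or
#'   `"mm_3dunet"` (CEC units / inverted residual blocks).
#' @param base_channels Width of the first encoder level; level `i` has
#'   `base_channels * 2^(i-1)` channels.
#' @param num_levels Number of encoder/decoder levels; input extents must be
#'   divisible by `2^num_levels`.
#' @param expansion_factor Channel expansion factor `t` of the CEC units
#'   (mobile variant only).
#' @param input_shape A [tensor_shape()] with `channels = 1`.
#' @param use_act Attach the auxiliary lesion-present classification head.
#' @param num_classes_seg Segmentation output channels (default 1, binary).
#' @param num_classes_cls Classification classes (default 2).
#' @param negative_slope Leaky activation slope.
#' @param act_attach `"encoder"` (deepest encoder features, the default) or
#'   `"decoder"` (full-resolution decoder features).
#' @param seed Integer seed for weight initialization.
#' @return A `network_config` object.
#' @export
#' @examples
#' network_config("mm_3dunet", base_channels = 4, num_levels = 2,
#'                expansion_factor = 6,
#'                input_shape = tensor_shape(1, 16, 32, 32))
network_config <- function(variant = c("baseline_3dunet", "mm_3dunet"),
                           base_channels,
                           num_levels = 4L,
                           expansion_factor = 1L,
                           input_shape,
                           use_act = FALSE,
                           num_classes_seg = 1L,
                           num_classes_cls = 2L,
                           negative_slope = 0.01,
                           act_attach = c("encoder", "decoder"),
                           seed = 1L) {
  variant <- match.arg(variant)
  act_attach <- match.arg(act_attach)
  stopifnot(inherits(input_shape, "tensor_shape"))
  if (input_shape$channels != 1L) {
    abort_contract("the network takes single-channel volumes")
  }
  if (base_channels < 1 || num_levels < 1 || expansion_factor < 1) {
    abort_contract("base_channels, num_levels and expansion_factor must be positive")
  }
  ext <- c(input_shape$depth, input_shape$height, input_shape$width)
  if (any(ext %% 2^num_levels != 0)) {
    abort_contract("input extents must be divisible by 2^num_levels")
  }
  structure(list(variant = variant,
                 base_channels = as.integer(base_channels),
                 num_levels = as.integer(num_levels),
                 expansion_factor = as.integer(expansion_factor),
                 input_shape = input_shape,
                 use_act = isTRUE(use_act),
                 num_classes_seg = as.integer(num_classes_seg),
                 num_classes_cls = as.integer(num_classes_cls),
                 negative_slope = negative_slope,
                 act_attach = act_attach,
                 seed = as.integer(seed)),
            class = "network_config")
}

he_uniform <- function(dims, fan_in) {
  b <- sqrt(3 / fan_in)
  array(stats::runif(prod(dims), -b, b), dims)
}

init_unit <- function(ci, co, config) {
  if (config$variant == "mm_3dunet") {
    ce <- config$expansion_factor * ci
    list(expand = he_uniform(c(ce, ci), ci),
         eg = rep(1, ce), eb = rep(0, ce),
         dw = he_uniform(c(ce, 3L, 3L, 3L), 27),
         dg = rep(1, ce), db = rep(0, ce),
         compress = he_uniform(c(co, ce), ce))
  } else {
    list(w = he_uniform(c(co, ci, 3L, 3L, 3L), 27 * ci),
         g = rep(1, co), b = rep(0, co))
  }
}

#' Build a parameterized network from a configuration
#'
#' Instantiates all weights (fan-in-scaled uniform initialization, seeded
#' from `config$seed`); the layer sequence is exactly the one
#' [network_complexity()] counts.
#'
#' @param config A [network_config()].
#' @return A `munet3d_network` object.
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  set.seed(config$seed)
  L <- config$num_levels
  widths <- config$base_channels * 2^(0:(L - 1))
  prev <- config$input_shape$channels
  enc <- vector("list", L)
  for (i in seq_len(L)) {
    w <- widths[i]
    enc[[i]] <- list(u1 = init_unit(prev, w, config), u2 = init_unit(w, w, config))
    prev <- w
  }
  act <- NULL
  if (config$use_act) {
    ci <- if (config$act_attach == "encoder") widths[L] else widths[1L]
    hc <- max(ci %/% 2L, 1L)
    act <- list(conv = he_uniform(c(hc, ci, 3L, 3L), 9 * ci),
                linW = he_uniform(c(config$num_classes_cls, hc), hc),
                linb = rep(0, config$num_classes_cls))
  }
  dec <- vector("list", L)
  cur <- widths[L]
  for (j in rev(seq_len(L))) {
    w <- widths[j]
    dec[[j]] <- list(up = he_uniform(c(w, cur, 2L, 2L, 2L), 8 * cur),
                     u1 = init_unit(2L * w, w, config),
                     u2 = init_unit(w, w, config))
    cur <- w
  }
  final <- he_uniform(c(config$num_classes_seg, cur), cur)
  structure(list(config = config,
                 weights = list(enc = enc, dec = dec, final = final, act = act)),
            class = "munet3d_network")
}

#' @export
print.munet3d_network <- function(x, ...) {
  g <- glance(network_complexity(x$config))
  cat(sprintf("<munet3d_network %s: base %d, %d levels%s%s; %s parameters>\n",
              x$config$variant, x$config$base_channels, x$config$num_levels,
              if (x$config$variant == "mm_3dunet") sprintf(", t=%d", x$config$expansion_factor) else "",
              if (x$config$use_act) ", +ACT" else "",
              format(g$total_params, big.mark = ",")))
  invisible(x)
}

#' Count the instantiated learnable parameters of a network
#'
#' Framework introspection: sums the lengths of every weight array actually
#' held by the network, independently of the analytic ledger.
#'
#' @param network A `munet3d_network`.
#' @return Integer-valued numeric.
#' @export
n_params <- function(network) {
  stopifnot(inherits(network, "munet3d_network"))
  total <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else if (is.numeric(x)) total <<- total + length(x)
    invisible(NULL)
  }
  walk(network$weights)
  total
}

# --- forward/backward -------------------------------------------------------

# Units use the fused C++ leaky-ReLU + instance-norm kernel; its math is
# identical to leaky_relu_fwd() followed by instnorm_fwd().
unit_fwd <- function(x, uw, config, residual, train = FALSE) {
  sl <- config$negative_slope
  if (config$variant == "mm_3dunet") {
    h1 <- conv3d_pointwise_fwd(x, uw$expand)
    n1 <- act_norm_fwd_cpp(h1, dim(h1), uw$eg, uw$eb, sl, 1e-5)
    h2 <- conv3d_depthwise_fwd(n1$y, uw$dw)
    n2 <- act_norm_fwd_cpp(h2, dim(h2), uw$dg, uw$db, sl, 1e-5)
    y <- conv3d_pointwise_fwd(n2$y, uw$compress)
    res <- residual && dim(x)[1L] == dim(y)[1L]
    if (res) y <- y + x
    cache <- if (train) list(x = x, n1 = n1, n2 = n2, res = res) else NULL
    list(y = y, cache = cache)
  } else {
    h <- conv3d_standard_fwd(x, uw$w)
    n <- act_norm_fwd_cpp(h, dim(h), uw$g, uw$b, sl, 1e-5)
    cache <- if (train) list(x = x, n = n) else NULL
    list(y = n$y, cache = cache)
  }
}

unit_bwd <- function(dy, uw, cache, config) {
  sl <- config$negative_slope
  if (config$variant == "mm_3dunet") {
    dres <- if (cache$res) dy else 0
    b3 <- conv3d_pointwise_bwd(cache$n2$y, uw$compress, dy)
    nb2 <- act_norm_bwd_cpp(b3$dx, dim(b3$dx), uw$dg, cache$n2$xhat,
                            cache$n2$inv, cache$n2$mu, sl)
    b2 <- conv3d_depthwise_bwd(cache$n1$y, uw$dw, nb2$dx)
    nb1 <- act_norm_bwd_cpp(b2$dx, dim(b2$dx), uw$eg, cache$n1$xhat,
                            cache$n1$inv, cache$n1$mu, sl)
    b1 <- conv3d_pointwise_bwd(cache$x, uw$expand, nb1$dx)
    dx <- b1$dx
    if (cache$res) dx <- dx + dres
    list(dx = dx,
         grads = list(expand = b1$dw, eg = nb1$dgamma, eb = nb1$dbeta,
                      dw = b2$dw, dg = nb2$dgamma, db = nb2$dbeta,
                      compress = b3$dw))
  } else {
    nb <- act_norm_bwd_cpp(dy, dim(dy), uw$g, cache$n$xhat,
                           cache$n$inv, cache$n$mu, sl)
    b <- conv3d_standard_bwd(cache$x, uw$w, nb$dx)
    list(dx = b$dx, grads = list(w = b$dw, g = nb$dgamma, b = nb$dbeta))
  }
}
# Forward pass with optional caches for backpropagation.
network_fwd <- function(network, x, train = FALSE) {
  cfg <- network$config
  W <- network$weights
  L <- cfg$num_levels
  skips <- vector("list", L)
  caches <- list(enc = vector("list", L), dec = vector("list", L))
  cur <- x
  for (i in seq_len(L)) {
    u1 <- unit_fwd(cur, W$enc[[i]]$u1, cfg, residual = cfg$variant == "mm_3dunet", train = train)
    u2 <- unit_fwd(u1$y, W$enc[[i]]$u2, cfg, residual = cfg$variant == "mm_3dunet", train = train)
    skips[[i]] <- u2$y
    p <- maxpool3d_fwd(u2$y)
    caches$enc[[i]] <- list(u1 = u1$cache, u2 = u2$cache, pool = if (train) p else NULL)
    cur <- p$y
  }
  bottom <- cur
  cls_logits <- NULL
  if (cfg$use_act && cfg$act_attach == "encoder") {
    ah <- act_head_fwd(bottom, W$act, cfg, train = train)
    cls_logits <- ah$logits
    caches$act <- ah$cache
  }
  for (j in rev(seq_len(L))) {
    up <- conv3d_transpose_fwd(cur, W$dec[[j]]$up)
    cc <- dim(up)[1L]
    cat_x <- array(0, c(2L * cc, dim(up)[-1L]))
    cat_x[seq_len(cc), , , ] <- up
    cat_x[cc + seq_len(cc), , , ] <- skips[[j]]
    u1 <- unit_fwd(cat_x, W$dec[[j]]$u1, cfg, residual = FALSE, train = train)
    u2 <- unit_fwd(u1$y, W$dec[[j]]$u2, cfg, residual = cfg$variant == "mm_3dunet", train = train)
    caches$dec[[j]] <- list(up_in = if (train) cur else NULL, u1 = u1$cache, u2 = u2$cache, cc = cc)
    cur <- u2$y
  }
  seg_logits <- conv3d_pointwise_fwd(cur, W$final)
  seg_probs <- sigmoid(seg_logits)
  if (cfg$use_act && cfg$act_attach == "decoder") {
    ah <- act_head_fwd(cur, W$act, cfg, train = train)
    cls_logits <- ah$logits
    caches$act <- ah$cache
  }
  caches$final_in <- if (train) cur else NULL
  caches$seg_probs <- seg_probs
  caches$bottom_dim <- dim(bottom)
  list(seg_probs = seg_probs, cls_logits = cls_logits,
       caches = if (train) caches else NULL)
}

act_head_fwd <- function(feat, aw, cfg, train = FALSE) {
  d <- dim(feat)
  dm <- apply(feat, c(1L, 3L, 4L), mean)      # collapse depth by averaging
  h <- conv2d_fwd(dm, aw$conv)
  a <- leaky_relu_fwd(h, cfg$negative_slope)
  hm <- a$y
  dim(hm) <- c(dim(hm)[1L], prod(dim(hm)[-1L]))
  pooled_idx <- max.col(hm, ties.method = "first")
  pooled <- hm[cbind(seq_len(nrow(hm)), pooled_idx)]
  logits <- as.vector(aw$linW %*% pooled + aw$linb)
  cache <- if (train) list(feat_dim = d, dm = dm, a = a["neg"],
                           hdim = dim(a$y), pooled_idx = pooled_idx, pooled = pooled) else NULL
  list(logits = logits, cache = cache)
}

act_head_bwd <- function(dlogits, aw, cache, cfg) {
  dlin_w <- outer(dlogits, cache$pooled)
  dpooled <- as.vector(crossprod(aw$linW, dlogits))
  dhm <- matrix(0, cache$hdim[1L], prod(cache$hdim[-1L]))
  dhm[cbind(seq_len(nrow(dhm)), cache$pooled_idx)] <- dpooled
  dim(dhm) <- cache$hdim
  da <- leaky_relu_bwd(cache$a, dhm, cfg$negative_slope)
  b <- conv2d_bwd(cache$dm, aw$conv, da)
  # distribute the depth-average gradient uniformly over depth
  d <- cache$feat_dim
  dfeat <- array(rep(as.vector(b$dx) / d[2L], each = 1), c(d[1L], d[3L], d[4L]))
  dfeat <- aperm(array(dfeat, c(d[1L], d[3L], d[4L], d[2L])), c(1L, 4L, 2L, 3L))
  list(dfeat = dfeat,
       grads = list(conv = b$dw, linW = dlin_w, linb = dlogits))
}

# Backward pass; dseg is the gradient w.r.t. the pre-sigmoid segmentation
# logits, dcls w.r.t. the classification logits (or NULL).
network_bwd <- function(network, caches, dseg, dcls = NULL) {
  cfg <- network$config
  W <- network$weights
  L <- cfg$num_levels
  grads <- list(enc = vector("list", L), dec = vector("list", L),
                final = NULL, act = NULL)
  fb <- conv3d_pointwise_bwd(caches$final_in, W$final, dseg)
  grads$final <- fb$dw
  dcur <- fb$dx
  if (!is.null(dcls) && cfg$use_act && cfg$act_attach == "decoder") {
    ab <- act_head_bwd(dcls, W$act, caches$act, cfg)
    grads$act <- ab$grads
    dcur <- dcur + ab$dfeat
  }
  dskips <- vector("list", L)
  for (j in seq_len(L)) {
    cj <- caches$dec[[j]]
    u2b <- unit_bwd(dcur, W$dec[[j]]$u2, cj$u2, cfg)
    u1b <- unit_bwd(u2b$dx, W$dec[[j]]$u1, cj$u1, cfg)
    cc <- cj$cc
    dup <- u1b$dx[seq_len(cc), , , , drop = FALSE]
    dskips[[j]] <- u1b$dx[cc + seq_len(cc), , , , drop = FALSE]
    tb <- conv3d_transpose_bwd(cj$up_in, W$dec[[j]]$up, dup)
    grads$dec[[j]] <- list(up = tb$dw, u1 = u1b$grads, u2 = u2b$grads)
    dcur <- tb$dx
  }
  if (!is.null(dcls) && cfg$use_act && cfg$act_attach == "encoder") {
    ab <- act_head_bwd(dcls, W$act, caches$act, cfg)
    grads$act <- ab$grads
    dcur <- dcur + ab$dfeat
  }
  for (i in rev(seq_len(L))) {
    ci <- caches$enc[[i]]
    dpool <- maxpool3d_bwd(ci$pool, dcur)
    dpool <- dpool + dskips[[i]]
    u2b <- unit_bwd(dpool, W$enc[[i]]$u2, ci$u2, cfg)
    u1b <- unit_bwd(u2b$dx, W$enc[[i]]$u1, ci$u1, cfg)
    grads$enc[[i]] <- list(u1 = u1b$grads, u2 = u2b$grads)
    dcur <- u1b$dx
  }
  grads
}

#' Run a forward pass
#'
#' @param network A `munet3d_network` built by [build_network()].
#' @param volume Numeric 3-D array `(D, H, W)` matching
#'   `config$input_shape`, or a 4-D `(1, D, H, W)` array.
#' @return A `network_output`: list with `seg_probs` (4-D array of
#'   probabilities in `[0, 1]`, same spatial shape as the input) and
#'   `cls_logits` (length-`num_classes_cls` vector, present iff the
#'   classifier head is enabled).
#' @export
forward <- function(network, volume) {
  stopifnot(inherits(network, "munet3d_network"))
  x <- as_input_array(network$config, volume)
  out <- network_fwd(network, x, train = FALSE)
  structure(list(seg_probs = out$seg_probs, cls_logits = out$cls_logits),
            class = "network_output")
}

as_input_array <- function(config, volume) {
  ish <- config$input_shape
  d <- dim(volume)
  if (length(d) == 3L) {
    x <- array(volume, c(1L, d))
  } else if (length(d) == 4L) {
    x <- volume
  } else {
    abort_contract("volume must be a 3-D (D,H,W) or 4-D (1,D,H,W) array")
  }
  if (dim(x)[1L] != ish$channels) {
    abort_contract("volume must be single-channel")
  }
  # the network is fully convolutional: any extents divisible by 2^num_levels
  # are admissible; the configured input_shape is the nominal/profiling shape
  if (any(dim(x)[-1L] %% 2^config$num_levels != 0)) {
    abort_contract(sprintf("volume extents (%s) must be divisible by 2^num_levels = %d",
                           paste(dim(x)[-1L], collapse = "x"), 2^config$num_levels))
  }
  x
}

#' Binarize a segmentation output
#'
#' Voxelwise indicator of `seg_probs >= threshold` (ties count as positive).
#'
#' @param output A `network_output` from [forward()], or a probability array.
#' @param threshold Real in (0, 1).
#' @return Integer 0/1 array with the spatial shape of the probabilities.
#' @export
predict_mask <- function(output, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) abort_contract("threshold must lie in (0, 1)")
  p <- if (inherits(output, "network_output")) output$seg_probs else output
  m <- array(0L, dim(p))
  m[p >= threshold] <- 1L
  m
}
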