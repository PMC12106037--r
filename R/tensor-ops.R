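# Low-level dense 3-D tensor operators.
#
# Feature maps are numeric arrays with dim = c(channels, depth, height, width),
# column-major, channel-first.  Channel-first means a length-C vector recycles
# correctly against a C x V matrix view of the array, which the depthwise and
# normalization kernels exploit.  All convolutions are stride-1 "same"-padded
# unless noted; spatial up/down-sampling only ever happens in the 2x2x2
# max-pool and the 2x2x2 stride-2 transpose convolution, both of which require
# even spatial extents.

feature_dim <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

as_cv <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1L], prod(d[-1L]))
  x
}

pad_spatial <- function(x, p) {
  d <- dim(x)
  if (all(p == 0L)) return(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * p[1L], d[3L] + 2L * p[2L], d[4L] + 2L * p[3L]))
  xp[, p[1L] + seq_len(d[2L]), p[2L] + seq_len(d[3L]), p[3L] + seq_len(d[4L])] <- x
  xp
}

#' @noRd
conv3d_pointwise_fwd <- function(x, w) {
  d <- feature_dim(x)
  stopifnot(ncol(w) == d[1L])
  y <- w %*% as_cv(x)
  dim(y) <- c(nrow(w), d[2L], d[3L], d[4L])
  y
}

conv3d_pointwise_bwd <- function(x, w, dy) {
  d <- feature_dim(x)
  dym <- as_cv(dy)
  xm <- as_cv(x)
  dx <- crossprod(w, dym)
  dim(dx) <- d
  list(dx = dx, dw = tcrossprod(dym, xm))
}


# Linear indices of the (C, D, H, W) sub-block starting at (1,1,1,1) inside a
# padded (C, Dp, Hp, Wp) array; shifting by off_abc translates the window.
window_index <- function(d, dp) {
  C <- d[1L]
  i_d <- (seq_len(d[2L]) - 1L) * C
  i_h <- (seq_len(d[3L]) - 1L) * (C * dp[2L])
  i_w <- (seq_len(d[4L]) - 1L) * (C * dp[2L] * dp[3L])
  idx <- seq_len(C)
  idx <- rep(idx, times = d[2L]) + rep(i_d, each = C)
  idx <- rep(idx, times = d[3L]) + rep(i_h, each = C * d[2L])
  rep(idx, times = d[4L]) + rep(i_w, each = C * d[2L] * d[3L])
}

# Depthwise 3-D convolution, per-channel kernels w[C, kd, kh, kw].
conv3d_depthwise_fwd <- function(x, w) {
  d <- feature_dim(x)
  k <- dim(w)[-1L]
  stopifnot(all(k %% 2L == 1L), dim(w)[1L] == d[1L])
  dwconv3d_fwd_cpp(x, as.integer(d), w, as.integer(dim(w)))
}

conv3d_depthwise_bwd <- function(x, w, dy) {
  d <- feature_dim(x)
  dwconv3d_bwd_cpp(x, as.integer(d), w, as.integer(dim(w)), dy)
}

# Standard 3-D convolution, w[Cout, Cin, kd, kh, kw], stride 1, same padding.
conv3d_standard_fwd <- function(x, w) {
  d <- feature_dim(x)
  k <- dim(w)[-(1:2)]
  p <- (k - 1L) %/% 2L
  stopifnot(all(k %% 2L == 1L), dim(w)[2L] == d[1L])
  co <- dim(w)[1L]
  wm <- w
  dim(wm) <- c(co, d[1L], prod(k))
  xp <- pad_spatial(x, p)
  dp <- dim(xp)
  idx0 <- window_index(d, dp)
  C <- d[1L]
  y <- matrix(0, co, prod(d[-1L]))
  for (cc in seq_len(k[3L])) for (b in seq_len(k[2L])) for (a in seq_len(k[1L])) {
    tnum <- a + (b - 1L) * k[1L] + (cc - 1L) * k[1L] * k[2L]
    off <- (a - 1L) * C + (b - 1L) * C * dp[2L] + (cc - 1L) * C * dp[2L] * dp[3L]
    xs <- xp[idx0 + off]
    dim(xs) <- c(d[1L], prod(d[-1L]))
    wk <- wm[, , tnum, drop = FALSE]
    dim(wk) <- c(co, d[1L])
    y <- y + wk %*% xs
  }
  dim(y) <- c(co, d[2L], d[3L], d[4L])
  y
}

conv3d_standard_bwd <- function(x, w, dy) {
  d <- feature_dim(x)
  k <- dim(w)[-(1:2)]
  p <- (k - 1L) %/% 2L
  xp <- pad_spatial(x, p)
  dp <- dim(xp)
  idx0 <- window_index(d, dp)
  C <- d[1L]
  dxp <- numeric(prod(dp))
  dw <- array(0, dim(w))
  co <- dim(w)[1L]
  wm <- w
  dim(wm) <- c(co, d[1L], prod(k))
  dym <- as_cv(dy)
  for (cc in seq_len(k[3L])) for (b in seq_len(k[2L])) for (a in seq_len(k[1L])) {
    tnum <- a + (b - 1L) * k[1L] + (cc - 1L) * k[1L] * k[2L]
    off <- (a - 1L) * C + (b - 1L) * C * dp[2L] + (cc - 1L) * C * dp[2L] * dp[3L]
    idx <- idx0 + off
    xs <- xp[idx]
    dim(xs) <- c(d[1L], prod(d[-1L]))
    dw[, , a, b, cc] <- tcrossprod(dym, xs)
    wk <- wm[, , tnum, drop = FALSE]
    dim(wk) <- c(co, d[1L])
    g <- crossprod(wk, dym)
    dxp[idx] <- dxp[idx] + as.vector(g)
  }
  dim(dxp) <- dp
  dx <- dxp[, p[1L] + seq_len(d[2L]), p[2L] + seq_len(d[3L]), p[3L] + seq_len(d[4L]), drop = FALSE]
  list(dx = dx, dw = dw)
}

# 2x2x2 stride-2 transpose convolution, w[Cout, Cin, 2, 2, 2].  Kernel and
# stride coincide so every output voxel receives exactly one contribution.
conv3d_transpose_fwd <- function(x, w) {
  d <- feature_dim(x)
  co <- dim(w)[1L]
  y <- array(0, c(co, 2L * d[2L], 2L * d[3L], 2L * d[4L]))
  xm <- as_cv(x)
  wm <- w
  dim(wm) <- c(co, d[1L], 8L)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    wk <- wm[, , a + (b - 1L) * 2L + (cc - 1L) * 4L, drop = FALSE]
    dim(wk) <- c(co, d[1L])
    g <- wk %*% xm
    dim(g) <- c(co, d[2L], d[3L], d[4L])
    y[, seq(a, 2L * d[2L], by = 2L), seq(b, 2L * d[3L], by = 2L), seq(cc, 2L * d[4L], by = 2L)] <- g
  }
  y
}

conv3d_transpose_bwd <- function(x, w, dy) {
  d <- feature_dim(x)
  xm <- as_cv(x)
  dx <- matrix(0, d[1L], prod(d[-1L]))
  dw <- array(0, dim(w))
  co <- dim(w)[1L]
  wm <- w
  dim(wm) <- c(co, d[1L], 8L)
  for (a in 1:2) for (b in 1:2) for (cc in 1:2) {
    dys <- dy[, seq(a, 2L * d[2L], by = 2L), seq(b, 2L * d[3L], by = 2L), seq(cc, 2L * d[4L], by = 2L), drop = FALSE]
    dim(dys) <- c(co, prod(d[-1L]))
    dw[, , a, b, cc] <- tcrossprod(dys, xm)
    wk <- wm[, , a + (b - 1L) * 2L + (cc - 1L) * 4L, drop = FALSE]
    dim(wk) <- c(co, d[1L])
    dx <- dx + crossprod(wk, dys)
  }
  dim(dx) <- d
  list(dx = dx, dw = dw)
}

# 2x2x2 max pooling; ties route the gradient to the first window position.
maxpool3d_fwd <- function(x) {
  d <- feature_dim(x)
  stopifnot(all(d[-1L] %% 2L == 0L))
  id <- seq(1L, d[2L], 2L); ih <- seq(1L, d[3L], 2L); iw <- seq(1L, d[4L], 2L)
  slices <- vector("list", 8L)
  i <- 0L
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    i <- i + 1L
    slices[[i]] <- x[, id + a, ih + b, iw + cc, drop = FALSE]
  }
  y <- slices[[1L]]
  for (i in 2:8) y <- pmax(y, slices[[i]])
  list(y = y, slices = slices)
}

maxpool3d_bwd <- function(cache, dy) {
  y <- cache$y
  d0 <- dim(y)
  d <- c(d0[1L], 2L * d0[2L], 2L * d0[3L], 2L * d0[4L])
  dx <- array(0, d)
  taken <- array(FALSE, d0)
  id <- seq(1L, d[2L], 2L); ih <- seq(1L, d[3L], 2L); iw <- seq(1L, d[4L], 2L)
  i <- 0L
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    i <- i + 1L
    hit <- (cache$slices[[i]] == y) & !taken
    taken <- taken | hit
    g <- dy * hit
    dx[, id + a, ih + b, iw + cc] <- g
  }
  dx
}

# Per-instance, per-channel normalization with learned affine (gamma, beta).
instnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- feature_dim(x)
  xm <- as_cv(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  y <- gamma * xhat + beta
  dim(y) <- d
  list(y = y, xhat = xhat, inv = inv)
}

instnorm_bwd <- function(cache, gamma, dy) {
  d <- feature_dim(dy)
  dym <- as_cv(dy)
  xhat <- cache$xhat
  dxhat <- gamma * dym
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  dim(dx) <- d
  list(dx = dx, dgamma = rowSums(dym * xhat), dbeta = rowSums(dym))
}

leaky_relu_fwd <- function(x, slope = 0.01) {
  y <- x
  neg <- x < 0
  y[neg] <- slope * y[neg]
  list(y = y, neg = neg)
}

leaky_relu_bwd <- function(cache, dy, slope = 0.01) {
  dx <- dy
  dx[cache$neg] <- slope * dx[cache$neg]
  dx
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# 2-D 3x3 convolution on [C, H, W] maps, used by the classifier head.
conv2d_fwd <- function(x, w) {
  d <- dim(x)
  co <- dim(w)[1L]
  k <- dim(w)[-(1:2)]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(d[1L], d[2L] + 2L * p[1L], d[3L] + 2L * p[2L]))
  xp[, p[1L] + seq_len(d[2L]), p[2L] + seq_len(d[3L])] <- x
  wm <- w
  dim(wm) <- c(co, d[1L], prod(k))
  y <- matrix(0, co, d[2L] * d[3L])
  for (a in seq_len(k[1L])) for (b in seq_len(k[2L])) {
    xs <- xp[, (a - 1L) + seq_len(d[2L]), (b - 1L) + seq_len(d[3L]), drop = FALSE]
    dim(xs) <- c(d[1L], d[2L] * d[3L])
    wk <- wm[, , a + (b - 1L) * k[1L], drop = FALSE]
    dim(wk) <- c(co, d[1L])
    y <- y + wk %*% xs
  }
  dim(y) <- c(co, d[2L], d[3L])
  y
}

conv2d_bwd <- function(x, w, dy) {
  d <- dim(x)
  k <- dim(w)[-(1:2)]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(d[1L], d[2L] + 2L * p[1L], d[3L] + 2L * p[2L]))
  xp[, p[1L] + seq_len(d[2L]), p[2L] + seq_len(d[3L])] <- x
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  co <- dim(w)[1L]
  wm <- w
  dim(wm) <- c(co, d[1L], prod(k))
  dym <- dy
  dim(dym) <- c(co, d[2L] * d[3L])
  for (a in seq_len(k[1L])) for (b in seq_len(k[2L])) {
    ia <- (a - 1L) + seq_len(d[2L]); ib <- (b - 1L) + seq_len(d[3L])
    xs <- xp[, ia, ib, drop = FALSE]
    dim(xs) <- c(d[1L], d[2L] * d[3L])
    dw[, , a, b] <- tcrossprod(dym, xs)
    wk <- wm[, , a + (b - 1L) * k[1L], drop = FALSE]
    dim(wk) <- c(co, d[1L])
    g <- crossprod(wk, dym)
    dim(g) <- c(d[1L], d[2L], d[3L])
    dxp[, ia, ib] <- dxp[, ia, ib] + g
  }
  dx <- dxp[, p[1L] + seq_len(d[2L]), p[2L] + seq_len(d[3L]), drop = FALSE]
  list(dx = dx, dw = dw)
}
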