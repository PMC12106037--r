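# Tensor-operator contracts: depthwise/pointwise convolutions, the CEC unit
# and the inverted residual block.

test_that("depthwise convolution preserves shape, passes identity kernels, and keeps channels independent", {
  set.seed(1)
  x <- array(rnorm(16 * 8 * 8 * 8), c(16, 8, 8, 8))
  spec <- conv_spec("depthwise", 16, 16)
  w <- array(rnorm(16 * 27), c(16, 3, 3, 3))
  y <- apply_depthwise_conv3d(x, spec, w)
  expect_identical(dim(y), dim(x))

  # kernels that are 1 at the center and 0 elsewhere reproduce the input
  wid <- array(0, c(16, 3, 3, 3))
  wid[, 2, 2, 2] <- 1
  expect_equal(apply_depthwise_conv3d(x, spec, wid), x)

  # an all-zero input channel stays all-zero whatever the other channels hold
  x2 <- x
  x2[1, , , ] <- 1
  x2[2, , , ] <- 0
  y2 <- apply_depthwise_conv3d(x2, spec, w)
  expect_true(all(y2[2, , , ] == 0))

  # channel independence against the brute-force oracle: perturbing channel i
  # changes only output channel i
  xs <- array(rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  ws <- array(rnorm(3 * 27), c(3, 3, 3, 3))
  sp3 <- conv_spec("depthwise", 3, 3)
  base <- apply_depthwise_conv3d(xs, sp3, ws)
  for (i in 1:3) {
    xp <- xs
    xp[i, , , ] <- xp[i, , , ] + rnorm(64)
    yp <- apply_depthwise_conv3d(xp, sp3, ws)
    changed <- vapply(1:3, function(j) any(yp[j, , , ] != base[j, , , ]), TRUE)
    expect_identical(changed, seq_len(3) == i)
  }
})

test_that("pointwise convolution mixes channels per voxel and matches a nested-loop oracle", {
  set.seed(2)
  x <- array(rnorm(16 * 8 * 8 * 8), c(16, 8, 8, 8))
  sp <- conv_spec("pointwise", 16, 32, kernel = c(1, 1, 1))
  w <- matrix(rnorm(32 * 16), 32, 16)
  y <- apply_pointwise_conv3d(x, sp, w)
  expect_identical(dim(y), c(32L, 8L, 8L, 8L))

  spi <- conv_spec("pointwise", 16, 16, kernel = c(1, 1, 1))
  expect_equal(apply_pointwise_conv3d(x, spi, diag(16)), x)

  xs <- array(rnorm(3 * 2 * 2 * 2), c(3, 2, 2, 2))
  ws <- matrix(rnorm(4 * 3), 4, 3)
  ys <- apply_pointwise_conv3d(xs, conv_spec("pointwise", 3, 4, kernel = c(1, 1, 1)), ws)
  for (o in 1:4) for (dd in 1:2) for (hh in 1:2) for (ww in 1:2) {
    expect_equal(ys[o, dd, hh, ww], sum(ws[o, ] * xs[, dd, hh, ww]))
  }

  expect_error(conv_spec("pointwise", 3, 4, kernel = c(3, 3, 3)),
               class = "munet3d_contract_error")
})

test_that("separable convolution equals its depthwise-then-pointwise factorization", {
  set.seed(3)
  x <- array(rnorm(3 * 4 * 4 * 4), c(3, 4, 4, 4))
  wd <- array(rnorm(3 * 27), c(3, 3, 3, 3))
  wp <- matrix(rnorm(5 * 3), 5, 3)
  y <- apply_pointwise_conv3d(
    apply_depthwise_conv3d(x, conv_spec("depthwise", 3, 3), wd),
    conv_spec("pointwise", 3, 5, kernel = c(1, 1, 1)), wp)
  # direct separable implementation as one standard conv with rank-1 kernels:
  # w[o, c, a, b, k] = wp[o, c] * wd[c, a, b, k]
  wfull <- array(0, c(5, 3, 3, 3, 3))
  for (o in 1:5) for (ci in 1:3) wfull[o, ci, , , ] <- wp[o, ci] * wd[ci, , , ]
  expect_equal(y, oracle_conv3d(x, wfull), tolerance = 1e-12)
})

test_that("the CEC unit expands to t*C_in internally and returns C_out channels", {
  spec <- cec_spec(16, 24, expansion_factor = 6)
  w <- cec_init_weights(spec, rng_seed = 1)
  expect_identical(dim(w$expand), c(96L, 16L))
  expect_identical(dim(w$dw), c(96L, 3L, 3L, 3L))
  expect_identical(dim(w$compress), c(24L, 96L))
  x <- array(rnorm(16 * 4 * 4 * 4), c(16, 4, 4, 4))
  y <- apply_cec_unit(x, spec, w)
  expect_identical(dim(y), c(24L, 4L, 4L, 4L))

  # convolutional parameter count: 16*96 + 96*27 + 96*24 = 6432
  expect_identical(length(w$expand) + length(w$dw) + length(w$compress), 6432L)

  expect_error(cec_spec(16, 24, expansion_factor = 0), class = "munet3d_contract_error")
})

test_that("a t=1 identity-configured CEC unit is the identity on non-negative input", {
  spec <- cec_spec(4, 4, expansion_factor = 1)
  w <- cec_init_weights(spec, rng_seed = 1)
  w$expand <- diag(4)
  w$compress <- diag(4)
  w$dw[] <- 0
  w$dw[, 2, 2, 2] <- 1
  x <- array(abs(rnorm(4 * 4 * 4 * 4)), c(4, 4, 4, 4))  # non-negative
  y <- apply_cec_unit(x, spec, w, normalize = FALSE)
  expect_equal(y, x, tolerance = 1e-12)
})

test_that("the compression stage is linear: scaling its input scales its output", {
  sp <- conv_spec("pointwise", 6, 2, kernel = c(1, 1, 1))
  w <- matrix(rnorm(12), 2, 6)
  x <- array(rnorm(6 * 8), c(6, 2, 2, 2))
  expect_equal(apply_pointwise_conv3d(2.5 * x, sp, w),
               2.5 * apply_pointwise_conv3d(x, sp, w), tolerance = 1e-12)
})

test_that("the inverted residual block adds the identity skip and is the identity at zero weights", {
  spec <- cec_spec(4, 4, expansion_factor = 3, use_residual = TRUE)
  w <- cec_init_weights(spec, rng_seed = 2)
  x <- array(rnorm(4 * 4 * 4 * 4), c(4, 4, 4, 4))
  expect_equal(apply_inverted_residual(x, spec, w),
               apply_cec_unit(x, spec, w) + x)

  # all-zero convolution weights: output == input exactly
  w0 <- w
  w0$expand[] <- 0; w0$dw[] <- 0; w0$compress[] <- 0
  expect_identical(apply_inverted_residual(x, spec, w0), x)

  # Jacobian at zero weights is the identity map (finite differences)
  x0 <- array(rnorm(4 * 2 * 2 * 2), c(4, 2, 2, 2))
  spec2 <- cec_spec(4, 4, expansion_factor = 2, use_residual = TRUE)
  w2 <- cec_init_weights(spec2, rng_seed = 3)
  w2$expand[] <- 0; w2$dw[] <- 0; w2$compress[] <- 0
  eps <- 1e-6
  for (i in sample(length(x0), 4)) {
    xp <- x0; xp[i] <- xp[i] + eps
    dy <- (apply_inverted_residual(xp, spec2, w2) - apply_inverted_residual(x0, spec2, w2)) / eps
    expected <- array(0, dim(x0)); expected[i] <- 1
    expect_equal(dy, expected, tolerance = 1e-6)
  }

  # a residual across mismatched channel counts is rejected at spec level
  expect_error(cec_spec(16, 24, expansion_factor = 6, use_residual = TRUE),
               class = "munet3d_contract_error")
  # without the residual flag the mismatched unit is just the CEC output
  spec3 <- cec_spec(3, 5, expansion_factor = 2)
  w3 <- cec_init_weights(spec3, rng_seed = 4)
  x3 <- array(rnorm(3 * 8), c(3, 2, 2, 2))
  expect_equal(apply_inverted_residual(x3, spec3, w3), apply_cec_unit(x3, spec3, w3))
})
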