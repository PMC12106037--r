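# Analytic parameter/FLOP accounting and the reference-configuration search.

test_that("parameter counts match the closed forms", {
  expect_identical(count_params(conv_spec("standard", 16, 32)), 13824)
  expect_identical(count_params(conv_spec("separable", 16, 32)), 432 + 512)
  expect_identical(count_params(conv_spec("standard", 1, 1, kernel = c(1, 1, 1))), 1)
  expect_identical(count_params(conv_spec("depthwise", 16, 16)), 432)
  expect_identical(count_params(conv_spec("pointwise", 16, 32, kernel = c(1, 1, 1))), 512)
})

test_that("MAC counts match the closed forms at the output extents", {
  expect_identical(count_flops(conv_spec("standard", 1, 16),
                               tensor_shape(16, 32, 256, 256)), 905969664)
  one <- tensor_shape(1, 1, 1, 1)
  expect_identical(count_flops(conv_spec("separable", 1, 1), one), 28)
  expect_identical(count_flops(conv_spec("standard", 1, 1, kernel = c(1, 1, 1)), one), 1)
  expect_identical(count_flops(conv_spec("separable", 1, 1, kernel = c(1, 1, 1)), one), 2)
})

test_that("the separable/standard cost ratio has one closed form for parameters and FLOPs", {
  expect_equal(separable_to_standard_ratio(conv_spec("standard", 64, 64)),
               1 / 64 + 1 / 27)
  expect_equal(separable_to_standard_ratio(conv_spec("standard", 1, 1, kernel = c(1, 1, 1))), 2)

  set.seed(7)
  for (i in 1:50) {
    ci <- sample(1:64, 1); co <- sample(1:64, 1); k <- sample(c(1, 3, 5), 3, replace = TRUE)
    std <- conv_spec("standard", ci, co, kernel = k)
    sep <- conv_spec("separable", ci, co, kernel = k)
    r <- separable_to_standard_ratio(std)
    expect_equal(count_params(sep) / count_params(std), r, tolerance = 1e-15)
    shp <- tensor_shape(co, sample(1:8, 1), sample(1:8, 1), sample(1:8, 1))
    expect_equal(count_flops(sep, shp) / count_flops(std, shp), r, tolerance = 1e-15)
  }
})

test_that("analytic counts equal instantiated layer weights for random specs", {
  set.seed(11)
  for (i in 1:100) {
    kind <- sample(c("standard", "depthwise", "pointwise", "separable", "transpose"), 1)
    ci <- sample(1:48, 1)
    co <- if (kind == "depthwise") ci else sample(1:48, 1)
    k <- if (kind == "pointwise") c(1L, 1L, 1L) else sample(c(1L, 2L, 3L), 3, replace = TRUE)
    sp <- conv_spec(kind, ci, co, kernel = k)
    expect_equal(count_params(sp),
                 sum(vapply(instantiate_conv_weights(sp), length, 1L)))
  }
})

test_that("network ledger totals equal introspected parameter counts across configurations", {
  shapes <- list(c(8, 8, 8), c(8, 16, 16))
  for (variant in c("baseline_3dunet", "mm_3dunet")) {
    for (L in 1:2) for (act in c(FALSE, TRUE)) {
      cfg <- network_config(variant, base_channels = 3, num_levels = L,
                            expansion_factor = 4,
                            input_shape = tensor_shape(1, 8, 16, 16),
                            use_act = act, seed = 1)
      ledger <- attr(network_complexity(cfg), "total_params")
      expect_identical(ledger, n_params(build_network(cfg)),
                       info = sprintf("%s L=%d act=%s", variant, L, act))
    }
  }
  cfg4 <- network_config("mm_3dunet", base_channels = 4, num_levels = 4,
                         expansion_factor = 6,
                         input_shape = tensor_shape(1, 16, 16, 16), seed = 1)
  expect_identical(attr(network_complexity(cfg4), "total_params"),
                   n_params(build_network(cfg4)))
})

test_that("a one-level toy network's ledger equals the hand count", {
  cfg <- network_config("baseline_3dunet", base_channels = 2, num_levels = 1,
                        input_shape = tensor_shape(1, 4, 4, 4))
  rep <- network_complexity(cfg)
  # hand count: enc 1->2 (54) + 2->2 (108), transpose 2->2 (32),
  # dec 4->2 (216) + 2->2 (108), head 2->1 (2), norm affine 2*(2+2+2+2) = 16
  expect_identical(attr(rep, "total_params"), 54 + 108 + 32 + 216 + 108 + 2 + 16)
  # FLOPs at 4x4x4 (V=64), pooled to 2x2x2 and transposed back:
  # 64*27*2 + 64*27*4 + 64*8*4 + 64*27*8 + 64*27*4 + 64*2
  expect_identical(attr(rep, "total_flops"),
                   64 * 27 * 2 + 64 * 27 * 4 + 64 * 8 * 4 + 64 * 27 * 8 + 64 * 27 * 4 + 64 * 2)
})

test_that("totals are monotone in base width, expansion factor, and input extents", {
  shp <- tensor_shape(1, 16, 16, 16)
  p_of_base <- vapply(c(2, 4, 8), function(b) {
    attr(network_complexity(network_config("mm_3dunet", b, num_levels = 2,
                                           expansion_factor = 4, input_shape = shp)), "total_params")
  }, 0)
  expect_true(all(diff(p_of_base) > 0))
  f_of_t <- vapply(c(2, 4, 8), function(t) {
    attr(network_complexity(network_config("mm_3dunet", 4, num_levels = 2,
                                           expansion_factor = t, input_shape = shp)), "total_flops")
  }, 0)
  expect_true(all(diff(f_of_t) > 0))
  f_of_ext <- vapply(c(16, 32, 64), function(e) {
    attr(network_complexity(network_config("mm_3dunet", 4, num_levels = 2,
                                           expansion_factor = 4,
                                           input_shape = tensor_shape(1, 16, e, e))), "total_flops")
  }, 0)
  expect_true(all(diff(f_of_ext) > 0))
})

test_that("the reference-config search is deterministic and reports empty matches", {
  cand0 <- fit_reference_config(0, 0,
                                base_widths = c(4L, 8L), depths = 16L, inplane = c(128L))
  expect_true(nrow(cand0) == 2 && !any(cand0$matches))
  cand1 <- fit_reference_config(1.78, 115.10,
                                base_widths = c(4L, 8L), depths = 16L, inplane = c(128L))
  cand2 <- fit_reference_config(1.78, 115.10,
                                base_widths = c(4L, 8L), depths = 16L, inplane = c(128L))
  expect_identical(cand1, cand2)
  canon <- canonical_reference_config(base_widths = c(4L, 8L), depths = 16L,
                                      inplane = c(128L))
  expect_identical(nrow(canon), 1L)
  expect_true(all(c("params_M", "flops_G", "cells_matched") %in% names(canon)))
})

test_that("half-up rounding rounds ties away from truncation", {
  expect_identical(round_half_up(0.005, 2), 0.01)
  expect_identical(round_half_up(1.784999, 2), 1.78)
  expect_identical(round_half_up(1.785, 2), 1.79)
})
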