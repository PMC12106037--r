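# Preprocessing, augmentation, slab sampling, splitting, and the training loop.

test_that("the cosine schedule matches its closed form", {
  expect_equal(cosine_lr(0, 130, 1e-4), 1e-4)
  expect_equal(cosine_lr(130, 130, 1e-4), 0)
  expect_equal(cosine_lr(65, 130, 1e-4), 5e-5)
  for (t in 0:20) {
    expect_equal(cosine_lr(t, 20, 3e-3), 3e-3 / 2 * (1 + cos(t * pi / 20)),
                 tolerance = 1e-15)
  }
  expect_error(cosine_lr(21, 20, 1e-4), class = "munet3d_contract_error")
})

test_that("z-score normalization standardizes, is idempotent, and is affine-invariant", {
  set.seed(12)
  v <- array(runif(1000, 10, 50), c(10, 10, 10))
  z <- zscore_normalize(v)
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-6)
  expect_equal(zscore_normalize(z), z, tolerance = 1e-6)
  expect_equal(zscore_normalize(3.2 * v + 17), z, tolerance = 1e-9)
  expect_error(zscore_normalize(array(5, c(3, 3, 3))), class = "munet3d_contract_error")
})

test_that("an identity augmentation draw leaves the sample unchanged", {
  s <- tiny_phantom_set(n = 1)[[1]]
  a <- augment(s, augment_params(max_rotation_deg = 0, flip_probability = 0,
                                 intensity_scale_range = 0), rng_seed = 1)
  expect_equal(a$volume, s$volume)
  expect_identical(a$mask, s$mask)
})

test_that("flipping twice restores the original sample", {
  s <- tiny_phantom_set(n = 1)[[1]]
  p <- augment_params(max_rotation_deg = 0, flip_probability = 1,
                      intensity_scale_range = 0)
  a2 <- augment(augment(s, p, rng_seed = 1), p, rng_seed = 2)
  expect_equal(a2$volume, s$volume)
  expect_identical(a2$mask, s$mask)
})

test_that("rotation roughly preserves mask volume and keeps mask and image aligned", {
  # centered ellipsoid, no noise, so the bright region is exactly the mask
  spec <- phantom_spec(n_volumes = 1, slices_per_volume = 16, in_plane_extent = 32,
                       lesion_probability = 1, lesions_per_volume = c(1, 1),
                       lesion_radius_range = c(6, 6), margin_irregularity = 0,
                       noise_sd = 0, seed = 21)
  set.seed(21)
  s <- generate_phantom_volume(spec)
  n0 <- sum(s$mask)
  p <- augment_params(max_rotation_deg = 15, flip_probability = 0.5,
                      intensity_scale_range = 0.2)
  for (sd in 1:5) {
    a <- augment(s, p, rng_seed = sd)
    expect_lt(abs(sum(a$mask) - n0) / n0, 0.05)
    # centroid of the mask tracks the centroid of the bright voxels
    idx <- which(a$mask == 1, arr.ind = TRUE)
    bright <- which(a$volume > stats::quantile(a$volume, 0.95), arr.ind = TRUE)
    expect_lt(sqrt(sum((colMeans(idx) - colMeans(bright))^2)), 3)
  }
})

test_that("slab sampling returns aligned contiguous windows covering all start positions", {
  s <- tiny_phantom_set(n = 1, depth = 24)[[1]]
  full <- sample_slab(s, 24L)
  expect_identical(full$volume, s$volume)
  starts <- integer(0)
  set.seed(31)
  for (i in 1:2000) {
    sl <- sample_slab(s, 16L)
    # recover the start from the first slice
    st <- which(vapply(1:9, function(k) identical(sl$volume[1, , ], s$volume[k, , ]), TRUE))
    starts <- union(starts, st)
    if (i <= 20) expect_identical(sl$mask, s$mask[st:(st + 15), , , drop = FALSE])
  }
  expect_setequal(starts, 1:9)
  expect_error(sample_slab(s, 32L), class = "munet3d_contract_error")
})

test_that("the dataset split is deterministic, disjoint and exhaustive", {
  sp <- split_dataset(1:219, 0.8, seed = 1)
  expect_length(sp$train, 175)
  expect_length(sp$test, 44)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:219)
  expect_identical(sp, split_dataset(1:219, 0.8, seed = 1))
  expect_false(identical(sp$train, split_dataset(1:219, 0.8, seed = 2)$train))
  sp2 <- split_dataset(1:2, 0.5, seed = 1)
  expect_length(sp2$train, 1)
  expect_length(sp2$test, 1)
})

test_that("short training runs are reproducible, finite, and log the cosine schedule", {
  ds <- tiny_phantom_set(n = 4)
  cfg <- network_config("mm_3dunet", base_channels = 2, num_levels = 2,
                        expansion_factor = 2,
                        input_shape = tensor_shape(1, 16, 32, 32), seed = 2)
  tc <- train_config(epochs = 3, batch_size = 2, lr0 = 1e-3, seed = 7,
                     val_fraction = 0.25)
  h1 <- train_model(build_network(cfg), ds, tc)
  h2 <- train_model(build_network(cfg), ds, tc)
  expect_identical(tibble::as_tibble(h1), tibble::as_tibble(h2))
  expect_identical(nrow(h1), 3L)
  expect_true(all(is.finite(h1$dice)))
  expect_equal(h1$lr, vapply(0:2, cosine_lr, 0, total = 3, lr0 = 1e-3),
               tolerance = 1e-12)
  expect_equal(h1$combined, h1$dice + tc$ce_weight * h1$ce)
  # weights actually moved
  expect_false(identical(trained_network(h1)$weights, build_network(cfg)$weights))
})

test_that("evaluation metrics agree with independently recomputed IoU/DSC per volume", {
  ds <- tiny_phantom_set(n = 3)
  net <- build_network(network_config("mm_3dunet", base_channels = 2, num_levels = 2,
                                      expansion_factor = 2,
                                      input_shape = tensor_shape(1, 16, 32, 32),
                                      seed = 2))
  res <- evaluate_model(net, ds, threshold = 0.5, normalize = TRUE)
  expect_identical(nrow(res), 3L)
  for (i in 1:3) {
    v <- zscore_normalize(ds[[i]]$volume)
    pred <- predict_mask(forward(net, array(v, c(1, dim(v)))), 0.5)
    cc <- confusion_counts(pred, array(ds[[i]]$mask, dim(pred)))
    expect_equal(res$iou[i], iou(cc))
    expect_equal(res$dsc[i], dsc(cc))
  }
  expect_equal(attr(res, "mean_iou"), mean(res$iou))
})

test_that("an all-background predictor scores zero IoU on lesioned volumes", {
  ds <- tiny_phantom_set(n = 2, lesion_probability = 1)
  zero <- array(0L, dim(ds[[1]]$mask))
  for (s in ds) {
    cc <- confusion_counts(zero, s$mask)
    expect_equal(iou(cc), 0)
  }
})
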