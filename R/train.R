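# Preprocessing, augmentation, slab sampling, dataset splitting, and the
# cosine-annealed Adam training loop with per-epoch validation metrics.

#' Training hyperparameters
#'
#' Defaults follow the reference training recipe: Adam with first-moment
#' decay 0.95 (the quoted "momentum factor"; Adam has no classical momentum,
#' so it is read as beta1), decoupled weight decay 1e-4, initial learning
#' rate 1e-4 annealed over one cosine cycle spanning all epochs, 130 epochs,
#' batch size 24, slabs of 16 consecutive slices, and an 8:2 train/test
#' split.  Desk-scale runs override `epochs` and `batch_size`.
#'
#' @param epochs Number of epochs (= cosine cycle length).
#' @param batch_size Slabs per optimizer step.
#' @param lr0 Initial learning rate.
#' @param weight_decay Decoupled weight-decay rate.
#' @param beta1,beta2 Adam moment decays.
#' @param slab_depth Consecutive slices per training slab (16 or 32).
#' @param split_ratio Train fraction for [split_dataset()].
#' @param val_fraction Fraction of the training samples carved off for the
#'   per-epoch validation curve.
#' @param ce_weight Weight `lambda` of the classification loss term.
#' @param epsilon Dice smoothing coefficient.
#' @param augment An [augment_params()] object, or `NULL` to disable
#'   augmentation.
#' @param seed Integer seed controlling every random draw of the run.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 130L, batch_size = 24L, lr0 = 1e-4,
                         weight_decay = 1e-4, beta1 = 0.95, beta2 = 0.999,
                         slab_depth = 16L, split_ratio = 0.8,
                         val_fraction = 0.1, ce_weight = 1,
                         epsilon = 1e-6, augment = augment_params(),
                         seed = 1L) {
  if (epochs < 1 || batch_size < 1 || lr0 <= 0) {
    abort_contract("epochs, batch_size and lr0 must be positive")
  }
  if (!slab_depth %in% c(16L, 32L) && slab_depth < 1) {
    abort_contract("slab_depth must be a positive slice count")
  }
  if (split_ratio <= 0 || split_ratio >= 1) abort_contract("split_ratio must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, weight_decay = weight_decay, beta1 = beta1,
                 beta2 = beta2, slab_depth = as.integer(slab_depth),
                 split_ratio = split_ratio, val_fraction = val_fraction,
                 ce_weight = ce_weight, epsilon = epsilon,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Random volumetric augmentation parameters
#'
#' @param max_rotation_deg Rotation bound (degrees) in the axial
#'   (height-width) plane.
#' @param flip_probability Probability of a horizontal (width-axis) flip.
#' @param intensity_scale_range Half-width of the linear intensity scaling
#'   band; 0.2 means scales drawn from `[0.8, 1.2]`.
#' @return An `augment_params` object.
#' @export
augment_params <- function(max_rotation_deg = 15, flip_probability = 0.5,
                           intensity_scale_range = 0.2) {
  if (flip_probability < 0 || flip_probability > 1) {
    abort_contract("flip_probability must lie in [0, 1]")
  }
  structure(list(max_rotation_deg = max_rotation_deg,
                 flip_probability = flip_probability,
                 intensity_scale_range = intensity_scale_range),
            class = "augment_params")
}

#' Cosine-annealed learning rate
#'
#' `lr_t = lr0 / 2 * (1 + cos(t * pi / T))`: one cycle, no restarts, `T`
#' equal to the number of epochs.
#'
#' @param step Current step `t`, `0 <= t <= total`.
#' @param total Cycle length `T`.
#' @param lr0 Initial learning rate.
#' @return The learning rate at `step`.
#' @export
#' @examples
#' cosine_lr(0, 130, 1e-4)    # 1e-4
#' cosine_lr(65, 130, 1e-4)   # 5e-5
cosine_lr <- function(step, total, lr0) {
  if (step < 0 || step > total) abort_contract("step must lie in [0, total]")
  lr0 / 2 * (1 + cos(step * pi / total))
}

#' Z-score intensity normalization
#'
#' Standardizes a volume to mean 0 and standard deviation 1 (population
#' denominator); invariant to affine intensity transforms of the input.
#'
#' @param volume Numeric array.
#' @return Array of the same shape.
#' @export
zscore_normalize <- function(volume) {
  mu <- mean(volume)
  sdv <- sqrt(mean((volume - mu)^2))
  if (sdv < 1e-12) {
    abort_contract("cannot z-score a constant volume (zero intensity variance)")
  }
  (volume - mu) / sdv
}

rotate_axial <- function(arr, theta_deg, nearest = FALSE, fill = 0) {
  d <- dim(arr)
  if (theta_deg == 0) return(arr)
  th <- theta_deg * pi / 180
  hc <- (d[2L] + 1) / 2; wc <- (d[3L] + 1) / 2
  hh <- matrix(seq_len(d[2L]), d[2L], d[3L])
  ww <- matrix(seq_len(d[3L]), d[2L], d[3L], byrow = TRUE)
  # inverse mapping: source coordinates for each target voxel
  hs <- cos(th) * (hh - hc) - sin(th) * (ww - wc) + hc
  ws <- sin(th) * (hh - hc) + cos(th) * (ww - wc) + wc
  out <- array(fill, d)
  if (nearest) {
    hr <- round(hs); wr <- round(ws)
    ok <- hr >= 1 & hr <= d[2L] & wr >= 1 & wr <= d[3L]
    idx <- hr[ok] + (wr[ok] - 1) * d[2L]
    for (z in seq_len(d[1L])) {
      sl <- arr[z, , ]
      o <- matrix(fill, d[2L], d[3L])
      o[ok] <- sl[idx]
      out[z, , ] <- o
    }
  } else {
    h0 <- floor(hs); w0 <- floor(ws)
    fh <- hs - h0; fw <- ws - w0
    ok <- h0 >= 1 & h0 + 1 <= d[2L] & w0 >= 1 & w0 + 1 <= d[3L]
    i00 <- h0[ok] + (w0[ok] - 1) * d[2L]
    i10 <- i00 + 1L
    i01 <- i00 + d[2L]
    i11 <- i01 + 1L
    c00 <- ((1 - fh) * (1 - fw))[ok]; c10 <- (fh * (1 - fw))[ok]
    c01 <- ((1 - fh) * fw)[ok];       c11 <- (fh * fw)[ok]
    for (z in seq_len(d[1L])) {
      sl <- arr[z, , ]
      o <- matrix(fill, d[2L], d[3L])
      o[ok] <- c00 * sl[i00] + c10 * sl[i10] + c01 * sl[i01] + c11 * sl[i11]
      out[z, , ] <- o
    }
  }
  out
}

#' Randomly augment a volume/mask pair
#'
#' Draws one rotation in the axial plane (bounded by `max_rotation_deg`),
#' one horizontal flip decision, and one linear intensity scale, and applies
#' the identical spatial transform to volume and mask (linear interpolation
#' for the volume, nearest-neighbour for the mask; intensity scaling touches
#' the volume only).  Draws come from the active RNG stream, or from
#' `rng_seed` when supplied.
#'
#' @param sample A [volume_sample()].
#' @param params An [augment_params()].
#' @param rng_seed Optional integer seed.
#' @return An augmented `volume_sample`.
#' @export
augment <- function(sample, params = augment_params(), rng_seed = NULL) {
  stopifnot(inherits(sample, "volume_sample"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  theta <- stats::runif(1, -params$max_rotation_deg, params$max_rotation_deg)
  do_flip <- stats::runif(1) < params$flip_probability
  scale <- 1 + stats::runif(1, -params$intensity_scale_range, params$intensity_scale_range)
  vol <- rotate_axial(sample$volume, theta, nearest = FALSE)
  msk <- if (!is.null(sample$mask)) rotate_axial(sample$mask, theta, nearest = TRUE) else NULL
  if (do_flip) {
    d3 <- dim(vol)[3L]
    vol <- vol[, , d3:1, drop = FALSE]
    if (!is.null(msk)) msk <- msk[, , d3:1, drop = FALSE]
  }
  vol <- vol * scale
  volume_sample(vol, msk, sample_id = sample$sample_id,
                voxel_spacing = sample$voxel_spacing)
}

#' Crop a random contiguous slab of slices
#'
#' Uniformly drawn start position; volume and mask are cropped identically.
#'
#' @param sample A [volume_sample()].
#' @param slab_depth Slice count of the slab (16 or 32 in the reference
#'   recipe).
#' @param rng_seed Optional integer seed.
#' @return A `volume_sample` of depth `slab_depth`.
#' @export
sample_slab <- function(sample, slab_depth = 16L, rng_seed = NULL) {
  stopifnot(inherits(sample, "volume_sample"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  d <- dim(sample$volume)[1L]
  if (d < slab_depth) abort_contract("volume has fewer slices than slab_depth")
  start <- if (d == slab_depth) 1L else sample.int(d - slab_depth + 1L, 1L)
  idx <- start + seq_len(slab_depth) - 1L
  volume_sample(sample$volume[idx, , , drop = FALSE],
                if (!is.null(sample$mask)) sample$mask[idx, , , drop = FALSE],
                sample_id = sample$sample_id,
                voxel_spacing = sample$voxel_spacing)
}

#' Deterministic train/test split of a sample manifest
#'
#' Shuffles the ids with the given seed and cuts at
#' `floor(ratio * n)`: disjoint, exhaustive, reproducible.
#'
#' @param ids Character/integer vector of sample ids.
#' @param ratio Train fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
#' @examples
#' split_dataset(1:219, 0.8, seed = 1)  # 175 train / 44 test
split_dataset <- function(ids, ratio = 0.8, seed = 1L) {
  if (length(ids) == 0) abort_contract("the manifest is empty")
  set.seed(seed)
  perm <- sample(ids)
  n_train <- floor(ratio * length(ids))
  list(train = perm[seq_len(n_train)],
       test = perm[setdiff(seq_along(perm), seq_len(n_train))])
}

# --- optimizer --------------------------------------------------------------

map_weights <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (nm in seq_along(a)) {
      if (is.null(a[[nm]])) next
      out[[nm]] <- map_weights(a[[nm]], b[[nm]], f)
    }
    out
  } else {
    f(a, b)
  }
}

zero_like <- function(a) {
  if (is.list(a)) lapply(a, function(x) if (is.null(x)) NULL else zero_like(x))
  else a * 0
}

adam_step <- function(net, grads, state, lr, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  state$m <- map_weights(state$m, grads, function(m, g) b1 * m + (1 - b1) * g)
  state$v <- map_weights(state$v, grads, function(v, g) b2 * v + (1 - b2) * g * g)
  # update = w - lr*wd*w - lr * mhat / (sqrt(vhat) + 1e-8), decoupled decay
  net$weights <- {
    step_one <- function(w, m, v) {
      w - lr * cfg$weight_decay * w - lr * (m / bc1) / (sqrt(v / bc2) + 1e-8)
    }
    rec <- function(w, m, v) {
      if (is.list(w)) {
        for (k in seq_along(w)) if (!is.null(w[[k]])) w[[k]] <- rec(w[[k]], m[[k]], v[[k]])
        w
      } else step_one(w, m, v)
    }
    rec(net$weights, state$m, state$v)
  }
  list(net = net, state = state)
}

slab_labels_onehot <- function(has_lesion, ncls) {
  g <- rep(0, ncls)
  g[if (has_lesion) 2L else 1L] <- 1
  g
}

train_step_grads <- function(network, slab, cfg_train) {
  cfg <- network$config
  x <- array(slab$volume, c(1L, dim(slab$volume)))
  out <- network_fwd(network, x, train = TRUE)
  labels <- array(slab$mask, dim(out$seg_probs))
  d_l <- dice_loss(out$seg_probs, labels, cfg_train$epsilon)
  dprob <- dice_loss_grad(out$seg_probs, labels, cfg_train$epsilon)
  dseg <- dprob * out$seg_probs * (1 - out$seg_probs)
  ce <- 0; dcls <- NULL
  if (cfg$use_act) {
    g <- slab_labels_onehot(any(slab$mask > 0), cfg$num_classes_cls)
    p <- softmax(out$cls_logits)
    ce <- cross_entropy_loss(p, g)
    dcls <- cfg_train$ce_weight * (p - g)
  }
  grads <- network_bwd(network, out$caches, dseg, dcls)
  list(grads = grads, dice = d_l, ce = ce)
}

#' Train a network on a phantom dataset
#'
#' Per epoch: every training sample is augmented, a random slab is cropped,
#' and slabs are consumed in shuffled order in mini-batches; the learning
#' rate follows [cosine_lr()] with the cycle length equal to the epoch
#' count.  The optimizer is Adam with decoupled weight decay.  A fraction of
#' the training samples is carved off for a per-epoch validation curve
#' (IoU/DSC at threshold 0.5).  Runs are fully reproducible from
#' `config$seed`; a non-finite loss aborts with a diagnostic.
#'
#' @param network A `munet3d_network` (its weights are the initialization).
#' @param dataset List of [volume_sample()]s with masks.
#' @param config A [train_config()].
#' @param verbose Print a line per epoch.
#' @return A `training_history` tibble (`epoch`, `lr`, `dice`, `ce`,
#'   `combined`, `val_iou`, `val_dsc`) with the trained network in
#'   `attr(, "network")`.
#' @export
train_model <- function(network, dataset, config = train_config(), verbose = FALSE) {
  stopifnot(inherits(network, "munet3d_network"), inherits(config, "train_config"))
  if (length(dataset) == 0) abort_contract("the dataset is empty")
  set.seed(config$seed)
  dataset <- lapply(dataset, function(s) {
    volume_sample(zscore_normalize(s$volume), s$mask, s$sample_id, s$voxel_spacing)
  })
  n <- length(dataset)
  n_val <- max(0L, floor(config$val_fraction * n))
  vidx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  tr <- setdiff(seq_len(n), vidx)
  state <- list(t = 0L, m = zero_like(network$weights), v = zero_like(network$weights))
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- cosine_lr(ep - 1L, config$epochs, config$lr0)
    order_ep <- sample(tr)
    dice_sum <- 0; ce_sum <- 0; nb <- 0L
    batch <- list()
    flush_batch <- function() {
      if (length(batch) == 0) return(invisible(NULL))
      acc <- NULL
      for (b in batch) {
        acc <- if (is.null(acc)) b$grads else map_weights(acc, b$grads, `+`)
      }
      acc <- map_weights(acc, acc, function(a, ...) a / length(batch))
      st <- adam_step(network, acc, state, lr, config)
      network <<- st$net; state <<- st$state
      batch <<- list()
    }
    for (i in order_ep) {
      s <- dataset[[i]]
      if (!is.null(config$augment)) s <- augment(s, config$augment)
      s <- sample_slab(s, min(config$slab_depth, dim(s$volume)[1L]))
      step <- train_step_grads(network, s, config)
      if (!is.finite(step$dice) || !is.finite(step$ce)) {
        stop(sprintf("training diverged at epoch %d (dice=%g, ce=%g)", ep, step$dice, step$ce))
      }
      dice_sum <- dice_sum + step$dice; ce_sum <- ce_sum + step$ce; nb <- nb + 1L
      batch[[length(batch) + 1L]] <- step
      if (length(batch) >= config$batch_size) flush_batch()
    }
    flush_batch()
    val_iou <- NA_real_; val_dsc <- NA_real_
    if (length(vidx) > 0) {
      vm <- evaluate_model(network, dataset[vidx], threshold = 0.5)
      val_iou <- attr(vm, "mean_iou"); val_dsc <- attr(vm, "mean_dsc")
    }
    hist[[ep]] <- tibble::tibble(
      epoch = ep, lr = lr, dice = dice_sum / nb, ce = ce_sum / nb,
      combined = dice_sum / nb + config$ce_weight * ce_sum / nb,
      val_iou = val_iou, val_dsc = val_dsc)
    if (verbose) {
      message(sprintf("epoch %3d  lr %.3g  dice %.4f  ce %.4f  val IoU %.3f",
                      ep, lr, dice_sum / nb, ce_sum / nb, val_iou))
    }
  }
  out <- dplyr::bind_rows(hist)
  class(out) <- c("training_history", class(out))
  attr(out, "network") <- network
  attr(out, "config") <- config
  out
}

#' Trained network stored with a training history
#'
#' @param history A `training_history` from [train_model()].
#' @return The trained `munet3d_network`.
#' @export
trained_network <- function(history) attr(history, "network")

#' @export
glance.training_history <- function(x, ...) {
  tibble::tibble(epochs = nrow(x),
                 final_dice = x$dice[nrow(x)],
                 final_combined = x$combined[nrow(x)],
                 final_val_iou = x$val_iou[nrow(x)],
                 final_val_dsc = x$val_dsc[nrow(x)])
}

#' Plot training curves
#'
#' @param object A `training_history`.
#' @param ... Unused.
#' @return A ggplot object with loss and validation-metric panels.
#' @export
autoplot.training_history <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              c("dice", "ce", "combined", "val_iou", "val_dsc"),
                              names_to = "series", values_to = "value")
  long$panel <- ifelse(long$series %in% c("val_iou", "val_dsc"), "validation", "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Evaluate a network on labeled volumes
#'
#' Deterministic full-volume forward passes; per-volume IoU and DSC at the
#' given binarization threshold, plus classification correctness when the
#' network carries the auxiliary head.
#'
#' @param network A `munet3d_network`.
#' @param dataset List of [volume_sample()]s with masks.
#' @param threshold Binarization threshold in (0, 1).
#' @param normalize Z-score volumes before the forward pass (set `FALSE`
#'   when the dataset is already standardized).
#' @return A `metrics_result` tibble (`sample_id`, `has_lesion`, `iou`,
#'   `dsc`, `cls_correct`) with attributes `mean_iou`, `mean_dsc`,
#'   `mean_iou_lesioned`, `cls_accuracy`.
#' @export
evaluate_model <- function(network, dataset, threshold = 0.5, normalize = FALSE) {
  rows <- lapply(dataset, function(s) {
    v <- if (normalize) zscore_normalize(s$volume) else s$volume
    out <- forward(network, array(v, c(1L, dim(v))))
    pred <- predict_mask(out, threshold)
    cc <- confusion_counts(pred, array(s$mask, dim(pred)))
    cls_ok <- NA
    if (!is.null(out$cls_logits)) {
      cls_ok <- (which.max(out$cls_logits) == 2L) == s$has_lesion
    }
    tibble::tibble(sample_id = s$sample_id, has_lesion = s$has_lesion,
                   iou = iou(cc), dsc = dsc(cc), cls_correct = cls_ok)
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("metrics_result", class(res))
  attr(res, "mean_iou") <- mean(res$iou)
  attr(res, "mean_dsc") <- mean(res$dsc)
  attr(res, "mean_iou_lesioned") <- if (any(res$has_lesion)) mean(res$iou[res$has_lesion]) else NA_real_
  attr(res, "mean_dsc_lesioned") <- if (any(res$has_lesion)) mean(res$dsc[res$has_lesion]) else NA_real_
  attr(res, "cls_accuracy") <- if (all(is.na(res$cls_correct))) NA_real_ else mean(res$cls_correct, na.rm = TRUE)
  res
}

#' @export
glance.metrics_result <- function(x, ...) {
  tibble::tibble(n = nrow(x),
                 mean_iou = attr(x, "mean_iou"),
                 mean_dsc = attr(x, "mean_dsc"),
                 mean_iou_lesioned = attr(x, "mean_iou_lesioned"),
                 mean_dsc_lesioned = attr(x, "mean_dsc_lesioned"),
                 cls_accuracy = attr(x, "cls_accuracy"))
}
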