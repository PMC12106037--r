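# Dice and cross-entropy losses, the combined multi-task objective, and the
# IoU / DSC evaluation metrics derived from voxelwise confusion counts.

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*g) + eps) / (sum(p) + sum(g) + eps)`, aggregated over all
#' voxels supplied (a volume, a slab, or a whole batch).  The smoothing
#' coefficient `eps` guards the empty-mask case.
#'
#' @param probs Numeric array of probabilities in `[0, 1]`.
#' @param labels Binary array of the same shape.
#' @param epsilon Small positive smoothing constant.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' dice_loss(c(0.5, 0.5, 0, 0), c(1, 0, 0, 0))  # ~0.5
dice_loss <- function(probs, labels, epsilon = 1e-6) {
  if (!identical(dim(probs), dim(labels)) || length(probs) != length(labels)) {
    abort_contract("probs and labels must have identical shape")
  }
  if (epsilon <= 0) abort_contract("epsilon must be positive")
  i <- sum(probs * labels)
  u <- sum(probs) + sum(labels)
  1 - (2 * i + epsilon) / (u + epsilon)
}

# Gradient of the Dice loss w.r.t. probs (used by the training loop).
dice_loss_grad <- function(probs, labels, epsilon = 1e-6) {
  i <- sum(probs * labels)
  u <- sum(probs) + sum(labels)
  -(2 * labels * (u + epsilon) - (2 * i + epsilon)) / (u + epsilon)^2
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Cross-entropy loss for the classification head
#'
#' `-sum(g * log(p))` averaged over the batch.  Inputs may be probability
#' vectors or raw logits (`from_logits = TRUE` applies a softmax first);
#' probabilities are floored at `1e-12` so a confident miss stays finite.
#'
#' @param cls_probs Probability (or logit) vector, or a matrix with one row
#'   per observation.
#' @param cls_labels One-hot vector/matrix of the same shape, or a vector of
#'   1-based class indices.
#' @param from_logits Convert inputs through a softmax before applying the
#'   loss.
#' @return Non-negative scalar loss.
#' @export
#' @examples
#' cross_entropy_loss(c(0.5, 0.5), c(1, 0))  # log(2)
cross_entropy_loss <- function(cls_probs, cls_labels, from_logits = FALSE) {
  p <- rbind(cls_probs)
  if (is.matrix(cls_labels)) {
    g <- cls_labels
  } else if (length(cls_labels) == ncol(p)) {
    g <- rbind(cls_labels)
  } else {
    g <- matrix(0, nrow(p), ncol(p))
    g[cbind(seq_len(nrow(p)), cls_labels)] <- 1
  }
  if (!all(dim(p) == dim(g))) abort_contract("probabilities and labels disagree in shape")
  if (from_logits) p <- t(apply(p, 1L, softmax))
  if (any(abs(rowSums(p) - 1) > 1e-6)) {
    abort_contract("each probability vector must sum to 1 (or pass from_logits = TRUE)")
  }
  p <- pmax(p, 1e-12)
  mean(-rowSums(g * log(p)))
}

#' Combined multi-task loss
#'
#' `combined = dice + ce_weight * ce`; a weight of 0 recovers pure
#' segmentation training.
#'
#' @param dice Dice loss value.
#' @param ce Cross-entropy value (0 when the classifier head is absent).
#' @param ce_weight Non-negative weight `lambda` on the classification term.
#' @return A `loss_value`: list with `dice`, `ce`, `ce_weight`, `combined`.
#' @export
combined_loss <- function(dice, ce = 0, ce_weight = 1) {
  if (ce_weight < 0) abort_contract("ce_weight must be non-negative")
  structure(list(dice = dice, ce = ce, ce_weight = ce_weight,
                 combined = dice + ce_weight * ce),
            class = "loss_value")
}

#' Voxelwise confusion counts between two binary masks
#'
#' @param pred,label Binary arrays of identical shape.
#' @return A `confusion_counts` list with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, label) {
  if (length(pred) != length(label) || !identical(dim(pred), dim(label))) {
    abort_contract("pred and label must have identical shape")
  }
  if (!all(pred %in% c(0, 1)) || !all(label %in% c(0, 1))) {
    abort_contract("confusion counts require binary (0/1) masks")
  }
  p <- as.logical(pred); g <- as.logical(label)
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 fn = sum(!p & g), tn = sum(!p & !g)),
            class = "confusion_counts")
}

#' Intersection over union
#'
#' `TP / (TP + FN + FP)`.  When prediction and reference are both empty the
#' union is empty and the score is 1 by convention.
#'
#' @param counts A [confusion_counts()] object.
#' @return Real in `[0, 1]`.
#' @export
iou <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- counts$tp + counts$fn + counts$fp
  if (den == 0) return(1)
  counts$tp / den
}

#' Dice similarity coefficient
#'
#' `2*TP / (2*TP + FN + FP)`; equals `2*IoU / (1 + IoU)`.  Both masks empty
#' scores 1 by convention.
#'
#' @param counts A [confusion_counts()] object.
#' @return Real in `[0, 1]`.
#' @export
dsc <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  den <- 2 * counts$tp + counts$fn + counts$fp
  if (den == 0) return(1)
  2 * counts$tp / den
}
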