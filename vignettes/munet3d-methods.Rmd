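---
title: "Methods: a mobile multi-task 3D U-Net and its complexity ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a mobile multi-task 3D U-Net and its complexity ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(munet3d)
```

## The model

`munet3d` implements a symmetric encoder–decoder segmentation network for
single-channel 3-D volumes.  The encoder consists of `num_levels` modules
(default 4), each holding two feature-extraction units followed by 2×2×2 max
pooling; module *i* outputs `base_channels * 2^(i-1)` channels, the first
unit of each module performing the doubling.  The decoder mirrors this: per
level, a 2×2×2 stride-2 transpose convolution doubles the spatial extents
and maps onto the level's width, the encoder skip feature map is
concatenated (upsampled features first, skip second), and two
feature-recovery units compress back to the level width.  A final 1×1×1
convolution with a sigmoid yields voxelwise foreground probabilities of the
same spatial shape as the input.

Two variants share this skeleton:

* **baseline** (`"baseline_3dunet"`): each unit is one standard 3×3×3
  convolution, leaky ReLU, instance normalization;
* **mobile** (`"mm_3dunet"`): each unit is a channel-expansion convolution
  (CEC) unit — a 1×1×1 convolution expanding `C_in` to `t·C_in` channels, a
  depthwise 3×3×3 convolution in the widened space, and a linear 1×1×1
  compression to `C_out`.  The expansion and depthwise stages each end in
  leaky ReLU + instance normalization; the compression stage is linear so
  the narrow representation is not clipped, and carries no normalization.
  Whenever a unit preserves its channel count the input is added to the
  output (an inverted residual block); units that change the width skip the
  residual silently.

The rationale for expansion-before-depthwise is the usual one for inverted
residuals: depthwise convolutions extract spatial structure per channel, so
richer cross-channel patterns require widening first; the linear bottleneck
then keeps the inter-unit representation compact.

The optional **auxiliary classification task (ACT)** head attaches to the
deepest encoder features (configurable to the decoder output via
`act_attach`, see *Design choices*): depth is collapsed by averaging, a 2-D
3×3 convolution maps to half the input width, and after leaky ReLU, global
max pooling and a biased linear layer produce logits over lesion-absent /
lesion-present.  Multi-task training adds the classification cross-entropy
to the Dice loss with weight `ce_weight` (λ, default 1; λ = 0 recovers pure
segmentation).

All convolutions are stride-1, "same"-padded and bias-free; padding is not
stated in typical architecture figures but symmetric shapes require it.
Leaky activations use slope 0.01; instance normalization uses ε = 1e-5 with
learned affine gain/offset, applied after the activation.

## Complexity accounting

The analytic ledger (`network_complexity()`) walks exactly the layer
sequence `build_network()` instantiates.  Per layer,

* standard / transpose: `P = C_in·K³·C_out`, `F = D·H·W·C_in·K³·C_out`,
* depthwise: `P = C_in·K³`, `F = D·H·W·C_in·K³`,
* pointwise: `P = C_in·C_out`, `F = D·H·W·C_in·C_out`,

where D, H, W are the layer's *output* extents, one multiply-accumulate
counts as one FLOP, and activations, normalization and pooling are free.
This is the convention under which replacing a standard convolution by its
separable factorization scales both costs by `1/C_out + 1/K³`.
Normalization affine parameters (2 per normalized channel) and the
classifier head are included in network totals as their own ledger rows, so
the totals equal the introspected weight count of a built network exactly —
a property the test suite checks layer-for-layer and end-to-end.  Totals
are kept as exact integers internally; rounding (half-up, two decimals, in
millions/billions) happens only at report time.

## Pinning unprinted hyperparameters, and a reproducibility gap

Published complexity tables for networks of this family often omit the base
width and the input shape used for profiling.  `fit_reference_config()`
therefore enumerates a finite space (base widths 4–32, input depths 16/32,
in-plane extents 128–256) and returns every configuration whose rounded
baseline totals match the published pair (1.78 M parameters, 115.10 G
FLOPs), scoring each candidate against all eight cells of the published
table (baseline, t = 6, t = 12, t = 12 + ACT).

For the table this package targets, **no configuration in that space
matches**, and the analysis suggests none can: with a channel schedule
shared between the baseline and the mobile variant, the parameter delta
between the t = 6 and t = 12 rows fixes Σ C_in(C_in + 27 + C_out) over the
CEC units near 2.0·10⁴, while the baseline row fixes Σ C_in·C_out over the
same positions near 6.3·10⁴ — contradictory, since the first sum dominates
the second term-by-term.  The published FLOPs are moreover printed to
0.01 G (a ±0.02 % window), effectively requiring the original authors'
exact profiling code.  The published table is internally consistent (its
percentage reductions follow from its own cells), but its absolute values
cannot be pinned by the two knobs the enumeration is allowed to turn.  The
package handles this honestly: the match set is reported as empty and the
canonical reference configuration falls back to the deterministic best
candidate — most cells matched, then smallest summed |log(ours/target)|
across the eight cells (symmetric in over- and under-estimation; a linear
relative error would degenerately favor the smallest network), then
enumeration order.  `scripts/acceptance.R` reports the ledger evaluated at
that candidate.

## Synthetic phantoms

The generator (`generate_phantom_volume()`) emulates the features of
contrast-enhanced breast MRI that matter for segmentation: a smooth
tissue-like background (coarse Gaussian noise, trilinearly upsampled, mapped
to a 0.3–0.7 intensity band), zero or more bright ellipsoidal lesions with
random centers, semi-axes and orientations whose support is perturbed by a
low-frequency field (irregular margins), lesion intensity equal to the local
background times `lesion_contrast` (default 2, an enhancing lesion), and
additive Gaussian noise (default sd 0.05).  The mask is the exact lesion
support and the per-volume lesion-present label drives the ACT head.

Defaults define the package's desk-scale study conditions: 32 volumes of
32×48×48 voxels at isotropic 1 mm spacing, lesion probability 0.75, 1–3
lesions of semi-axes 3–8 voxels.  The in-plane extent was set so that a
complete 30-epoch CPU training run finishes in minutes, which is what the
desk-scale tests are for; the generator scales to study-sized manifests
(219 volumes × 184 slices = 40,296 slice images) in metadata-only mode.

What the phantoms do *not* model: multi-phase contrast kinetics,
anisotropic acquisition, coil inhomogeneity, motion artifacts,
non-mass-like enhancement, or anatomically realistic tissue boundaries.
Tests passing on phantoms therefore demonstrate that the implementation can
learn and evaluate segmentation end-to-end — not that the architecture
reaches any particular accuracy on clinical data.

## Training recipe

`train_config()` defaults to the reference recipe: Adam with first-moment
decay β₁ = 0.95 (a quoted "momentum factor" is read as β₁, since Adam has
no classical momentum; β₂ = 0.999), decoupled weight decay 1e-4, initial
learning rate 1e-4 annealed over a single cosine cycle spanning all epochs
(`lr_t = lr₀/2·(1 + cos(tπ/T))`, T = epochs, no restarts), 130 epochs,
batch size 24, z-score intensity normalization per volume, random
volumetric augmentation (rotation up to ±15° in the axial plane — volume
interpolated bilinearly, mask nearest-neighbour — horizontal flips with
probability 0.5, ±20 % linear intensity scaling), and random contiguous
slabs of 16 (or 32) slices as network inputs.  The slab's own mask content
provides the classification label during training, since a cropped slab of
a lesioned volume may not contain the lesion.

At desk scale the package's canonical run uses 30 epochs, batch size 1 and
lr₀ = 1e-3: with single-slab updates on 48² crops, the reference rate of
1e-4 moves the weights too little to converge within 30 epochs, and 1e-3 is
the conventional Adam default for training from scratch.  A 10 % fraction
of the training samples is carved off for a per-epoch validation curve
(the reference protocol reports verification curves without defining a
third split).  Runs are bit-reproducible from a single seed: the seed
drives weight initialization, the validation carve, epoch shuffling,
augmentation and slab draws, and the implementation is deterministic
single-threaded R/C++.

## Numerical and design choices

* **Decoder ordering.**  Mirroring the encoder module `[unit, unit, pool]`
  gives the decoder module `[transpose, concat, unit, unit]`; an alternative
  reading puts the transpose at the module end, but then the final module
  leaves `base/2` channels at full resolution and skips cannot concatenate
  at matching resolutions, so the classical mirrored ordering is used.
* **ACT attachment.**  Descriptions of such heads ambiguously place them
  "at the end of the encoder" or "in the decoder stage".  The head here
  attaches to the deepest encoder features by default (the reading under
  which the head regularizes the shared encoder); `act_attach = "decoder"`
  is the escape hatch.  The depth-collapse is a global average over the
  slice axis, the simplest mapping of 3-D features to a 2-D space.
* **Skip merge** is channel concatenation, upsampled features first.
* **Empty masks.**  IoU and DSC are 1 when both prediction and reference
  are empty; `evaluate_model()` also reports lesioned-only means so that
  lesion-free volumes cannot inflate segmentation scores.
* **Ties.**  `predict_mask()` counts probability == threshold as positive;
  max-pooling routes gradients to the first maximum in the window.
* **Floors.**  Cross-entropy probabilities are floored at 1e-12; the Dice
  smoothing coefficient defaults to 1e-6 ("a very small positive number").
* **Degenerate inputs.**  Constant volumes are rejected by
  `zscore_normalize()`; volumes thinner than the slab depth, indivisible
  extents, non-binary masks and mismatched shapes raise contract errors of
  class `munet3d_contract_error`.
* **Problem sizes.**  Unit tests exercise 4³–32³ tensors; the desk-scale
  training property uses the 32-phantom default conditions above; the
  complexity enumeration covers the full documented space (36 shape/width
  combinations) in seconds, since it is pure integer arithmetic.

## Known limitations

Single-channel single-phase input only (no multi-phase DCE kinetics);
no attention, deep supervision, Hausdorff/surface metrics, or
patch-stitched whole-volume inference; training is single-threaded CPU and
intended for desk-scale experiments, not clinical-scale runs; and the
published complexity table this package targets can only be approached, not
reproduced exactly, for the reasons given above.
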