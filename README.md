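# munet3d

Lightweight multi-task mobile 3D U-Net for volumetric lesion segmentation,
with exact analytic complexity accounting.

Deep 3D U-Nets segment tumors in volumetric MRI well, but their parameter
counts and computational load make them hard to deploy outside GPU servers.
A standard remedy is to replace every standard 3×3×3 convolution by a **3D
depthwise-separable convolution** — a per-channel spatial convolution
followed by a 1×1×1 cross-channel mixing convolution — arranged into
*channel-expansion convolution (CEC) units* (1×1×1 expansion to `t·C_in`
channels, depthwise 3×3×3 convolution in the widened space, linear 1×1×1
compression) wrapped as *inverted residual blocks* (IRB), plus an *auxiliary
classification task* (ACT) head that predicts lesion presence from the
shared encoder as an extra supervisory signal.

`munet3d` is a self-contained R implementation of this design for people who
want to study its **complexity/accuracy trade-off** quantitatively:

* exact closed-form parameter and FLOP (multiply-accumulate) counting for
  every layer and whole networks, for both the classical 3D U-Net baseline
  and the mobile variant —

  ```
  P_separable = C_in·K_D·K_H·K_W + C_in·C_out       P_standard = C_in·K_D·K_H·K_W·C_out
  F_separable = D·H·W·C_in·(K_D·K_H·K_W + C_out)    F_standard = D·H·W·C_in·K_D·K_H·K_W·C_out
  ```

  so the separable/standard cost ratio is `1/C_out + 1/(K_D·K_H·K_W)` for
  parameters and FLOPs alike;
* a constrained search (`fit_reference_config()`) that enumerates base
  widths and input shapes against a published complexity table to pin down
  unprinted architecture hyperparameters;
* a complete CPU training stack written on base R arrays, BLAS matrix
  products and two small C++ kernels: soft Dice loss, cross-entropy for the
  ACT head, Adam with decoupled weight decay, one-cycle cosine learning-rate
  annealing, volumetric augmentation (axial rotation, horizontal flip,
  intensity scaling), 16/32-slice slab sampling, and IoU/DSC evaluation;
* NIfTI-1 volume I/O and a seeded synthetic phantom generator (smooth
  tissue background, bright ellipsoidal lesions with irregular margins,
  exact masks, lesion-present labels) standing in for private DCE-MRI data.

## Worked example

```r
library(munet3d)

# analytic complexity of a mobile network at expansion factor 6
cfg <- network_config("mm_3dunet", base_channels = 8, expansion_factor = 6,
                      input_shape = tensor_shape(1, 32, 256, 256))
glance(network_complexity(cfg))
#> # A tibble: 1 × 4
#>   total_params total_flops params_M flops_G
#>          <dbl>       <dbl>    <dbl>   <dbl>
#> 1       504808 34874851328      0.5    34.9
```

Half a million learnable weights and 34.9 G multiply-accumulates per
forward pass at a 32×256×256 input — the same ledger the baseline variant
answers with 0.72 M / 33.13 G at base width 8, and which grows/shrinks
linearly in the expansion factor `t`.

```r
# generate phantoms, train at desk scale, evaluate
spec <- phantom_spec(seed = 11)                # 32 volumes, 32 x 48 x 48
set.seed(spec$seed)
ds <- lapply(seq_len(spec$n_volumes), function(i)
  generate_phantom_volume(spec, sample_id = sprintf("phantom%03d", i)))
sp <- split_dataset(seq_along(ds), 0.8, seed = 11)

net <- build_network(network_config("mm_3dunet", base_channels = 4,
                                    num_levels = 2, expansion_factor = 6,
                                    input_shape = tensor_shape(1, 16, 48, 48),
                                    use_act = TRUE, seed = 11))
hist <- train_model(net, ds[sp$train],
                    train_config(epochs = 30, batch_size = 1, lr0 = 1e-3,
                                 seed = 11))
glance(evaluate_model(trained_network(hist), ds[sp$test], normalize = TRUE))
```

On the held-out phantoms this 30-epoch CPU run reaches a mean IoU above 0.8
on lesioned volumes and classifies lesion presence correctly on unseen
phantoms; `autoplot(hist)` draws the loss and validation curves.

A thin command-line dispatcher over the same functions ships in
`inst/cli/munet3d.R` (subcommands `count`, `fit-config`, `gen`, `train`,
`eval`, `predict`).

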