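# Shared fixtures: tiny phantoms and network configurations sized for tests.

tiny_phantom_set <- function(n = 4, depth = 16, inplane = 32, lesion_probability = 1,
                             seed = 5) {
  spec <- phantom_spec(n_volumes = n, slices_per_volume = depth,
                       in_plane_extent = inplane,
                       lesion_probability = lesion_probability,
                       lesion_radius_range = c(3, 6), seed = seed)
  set.seed(seed)
  lapply(seq_len(n), function(i)
    generate_phantom_volume(spec, sample_id = sprintf("p%02d", i)))
}

tiny_mm_config <- function(base = 2, levels = 1, t = 2, ext = c(4, 4, 4),
                           use_act = FALSE, seed = 3) {
  network_config("mm_3dunet", base_channels = base, num_levels = levels,
                 expansion_factor = t,
                 input_shape = tensor_shape(1, ext[1], ext[2], ext[3]),
                 use_act = use_act, seed = seed)
}

# Brute-force correlation oracle for small standard 3-D convolutions
# ("same" padding, stride 1); independent of the package's operators.
oracle_conv3d <- function(x, w) {
  d <- dim(x); k <- dim(w)[-(1:2)]; co <- dim(w)[1]
  p <- (k - 1) %/% 2
  xp <- array(0, c(d[1], d[2] + 2 * p[1], d[3] + 2 * p[2], d[4] + 2 * p[3]))
  xp[, p[1] + seq_len(d[2]), p[2] + seq_len(d[3]), p[3] + seq_len(d[4])] <- x
  y <- array(0, c(co, d[2], d[3], d[4]))
  for (o in seq_len(co)) for (dd in seq_len(d[2])) for (hh in seq_len(d[3])) for (ww in seq_len(d[4])) {
    acc <- 0
    for (ci in seq_len(d[1])) for (a in seq_len(k[1])) for (b in seq_len(k[2])) for (cc in seq_len(k[3]))
      acc <- acc + w[o, ci, a, b, cc] * xp[ci, dd + a - 1, hh + b - 1, ww + cc - 1]
    y[o, dd, hh, ww] <- acc
  }
  y
}

# Weight arrays an instantiated layer of the given spec would hold; the
# independent oracle for the analytic parameter counts.
instantiate_conv_weights <- function(spec) {
  k <- spec$kernel; ci <- spec$in_channels; co <- spec$out_channels
  switch(spec$kind,
    standard  = list(array(0, c(co, ci, k))),
    transpose = list(array(0, c(co, ci, k))),
    depthwise = list(array(0, c(ci, k))),
    pointwise = list(matrix(0, co, ci)),
    separable = list(array(0, c(ci, k)), matrix(0, co, ci))
  )
}
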