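# NIfTI volume I/O, dataset manifests, and the synthetic phantom generator
# that stands in for private DCE-MRI data.
#
# Axis convention: in-memory arrays are ordered (depth, height, width),
# depth being the slice axis; "axial-plane" operations act on the
# height-width plane.  On disk the NIfTI dimension order is (width, height,
# depth) -- i.e. slices along the third NIfTI dimension -- so reading and
# writing transpose with aperm(c(3, 2, 1)).

#' Bundle a volume with its mask and metadata
#'
#' @param volume Numeric 3-D array `(D, H, W)`.
#' @param mask Binary 3-D array of identical shape (may be `NULL` for
#'   unlabeled volumes).
#' @param sample_id Identifier string.
#' @param voxel_spacing Positive triple, mm per voxel along `(D, H, W)`.
#' @return A `volume_sample` object; `has_lesion` is derived from the mask.
#' @export
volume_sample <- function(volume, mask = NULL, sample_id = "sample",
                          voxel_spacing = c(1, 1, 1)) {
  stopifnot(length(dim(volume)) == 3L)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(volume))) {
      abort_contract("volume and mask shapes must be identical")
    }
    if (!all(mask %in% c(0, 1))) abort_contract("mask must be binary")
  }
  if (any(voxel_spacing <= 0)) abort_contract("voxel spacing must be positive")
  structure(list(volume = volume, mask = mask,
                 has_lesion = !is.null(mask) && any(mask > 0),
                 sample_id = sample_id,
                 voxel_spacing = as.numeric(voxel_spacing)),
            class = "volume_sample")
}

#' @export
print.volume_sample <- function(x, ...) {
  cat(sprintf("<volume_sample '%s' %s, %s, lesion: %s>\n", x$sample_id,
              paste(dim(x$volume), collapse = "x"),
              paste(sprintf("%.2fmm", x$voxel_spacing), collapse = "/"),
              x$has_lesion))
  invisible(x)
}

#' Read a NIfTI-1 volume
#'
#' Returns the image canonicalized to the package's `(depth, height, width)`
#' axis order with voxel spacing taken from the header.  4-D (multi-phase)
#' files are rejected: the pipeline is single-phase.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return A `volume_sample` with `mask = NULL`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- array(img, d[1:3]); d <- d[1:3]
  }
  if (length(d) != 3L) {
    stop("expected a 3-D single-phase volume, got ", length(d), " dimensions")
  }
  sp <- RNifti::pixdim(img)[1:3]
  arr <- aperm(as.array(img), c(3L, 2L, 1L))
  volume_sample(arr, sample_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                voxel_spacing = rev(sp))
}

#' Write a volume (or mask) as NIfTI-1
#'
#' Images are stored as 32-bit float, masks as unsigned 8-bit; voxel spacing
#' goes into the header.
#'
#' @param volume Numeric 3-D array in `(D, H, W)` order.
#' @param path Output path (`.nii.gz` recommended).
#' @param voxel_spacing Spacing triple along `(D, H, W)`, mm.
#' @param mask Write as an 8-bit unsigned mask instead of float32.
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, path, voxel_spacing = c(1, 1, 1), mask = FALSE) {
  if (!all(is.finite(volume))) abort_contract("volume contains non-finite values")
  arr <- aperm(volume, c(3L, 2L, 1L))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(as.numeric(voxel_spacing))
  RNifti::writeNifti(img, path, datatype = if (mask) "uint8" else "float")
  invisible(path)
}

#' Parameters of the synthetic phantom generator
#'
#' The generator emulates the salient features of contrast-enhanced breast
#' MRI used for lesion segmentation: a smooth tissue-like background texture,
#' zero or more bright ellipsoidal lesions with irregular margins, additive
#' acquisition noise, an exact binary lesion mask, and a per-volume
#' lesion-present label.  Defaults are the package's desk-scale study
#' conditions: 32 volumes of 32 x 48 x 48 voxels at isotropic 1 mm spacing.
#'
#' @param n_volumes Number of volumes in a generated dataset.
#' @param slices_per_volume Depth extent (slice count) per volume.
#' @param in_plane_extent Height = width extent.
#' @param lesion_probability Probability that a volume carries lesions.
#' @param lesions_per_volume Integer range `c(min, max)` of lesion count in
#'   lesioned volumes.
#' @param lesion_radius_range Range of ellipsoid semi-axes, voxels.
#' @param lesion_contrast Lesion-to-background intensity ratio (> 1 gives
#'   enhancing lesions).
#' @param background_smoothness Spatial scale (voxels) of the background
#'   texture; larger is smoother.
#' @param margin_irregularity Relative amplitude of the low-frequency
#'   boundary perturbation that roughens lesion margins.
#' @param noise_sd Standard deviation of additive Gaussian noise.
#' @param voxel_spacing Spacing triple, mm.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(n_volumes = 32L,
                         slices_per_volume = 32L,
                         in_plane_extent = 48L,
                         lesion_probability = 0.75,
                         lesions_per_volume = c(1L, 3L),
                         lesion_radius_range = c(3, 8),
                         lesion_contrast = 2.0,
                         background_smoothness = 16,
                         margin_irregularity = 0.15,
                         noise_sd = 0.05,
                         voxel_spacing = c(1, 1, 1),
                         seed = 1L) {
  if (lesion_probability < 0 || lesion_probability > 1) {
    abort_contract("lesion_probability must lie in [0, 1]")
  }
  ext <- c(slices_per_volume, in_plane_extent, in_plane_extent)
  if (2 * max(lesion_radius_range) > min(ext)) {
    abort_contract("lesion radii must fit inside the volume")
  }
  structure(list(n_volumes = as.integer(n_volumes),
                 slices_per_volume = as.integer(slices_per_volume),
                 in_plane_extent = as.integer(in_plane_extent),
                 lesion_probability = lesion_probability,
                 lesions_per_volume = as.integer(lesions_per_volume),
                 lesion_radius_range = as.numeric(lesion_radius_range),
                 lesion_contrast = lesion_contrast,
                 background_smoothness = background_smoothness,
                 margin_irregularity = margin_irregularity,
                 noise_sd = noise_sd,
                 voxel_spacing = as.numeric(voxel_spacing),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Linear-interpolation upsampling matrix from n_coarse to n_fine samples.
interp_matrix <- function(n_fine, n_coarse) {
  if (n_coarse == 1L) return(matrix(1, n_fine, 1L))
  pos <- seq(1, n_coarse, length.out = n_fine)
  lo <- pmin(floor(pos), n_coarse - 1L)
  fr <- pos - lo
  m <- matrix(0, n_fine, n_coarse)
  m[cbind(seq_len(n_fine), lo)] <- 1 - fr
  m[cbind(seq_len(n_fine), lo + 1L)] <- fr
  m
}

# Smooth random field: coarse white noise trilinearly upsampled to extent.
smooth_field <- function(ext, scale) {
  nc <- pmax(2L, ceiling(ext / scale))
  coarse <- array(stats::rnorm(prod(nc)), nc)
  up <- function(x, m, axis) {
    d <- dim(x)
    perm <- c(axis, setdiff(1:3, axis))
    xp <- aperm(x, perm)
    dp <- dim(xp)
    dim(xp) <- c(dp[1L], prod(dp[-1L]))
    y <- m %*% xp
    dim(y) <- c(nrow(m), dp[-1L])
    aperm(y, order(perm))
  }
  f <- coarse
  for (ax in 1:3) f <- up(f, interp_matrix(ext[ax], nc[ax]), ax)
  f
}

#' Generate one synthetic phantom volume
#'
#' Background = smoothed random field mapped to a tissue-like intensity band
#' (0.3-0.7).  With probability `lesion_probability`, 1 to
#' `lesions_per_volume[2]` ellipsoids with random centers, semi-axes and
#' orientations are inserted; their support is perturbed by a low-frequency
#' field so the margins are irregular, and their intensity is the local
#' background times `lesion_contrast`.  Gaussian noise is added last; the
#' mask is the exact lesion support.
#'
#' @param spec A [phantom_spec()].
#' @param rng_seed Optional seed; when `NULL` the current RNG stream is used
#'   (so dataset generation draws a reproducible sequence).
#' @param sample_id Identifier for the returned sample.
#' @return A `volume_sample` with exact `mask` and `has_lesion` label.
#' @export
generate_phantom_volume <- function(spec, rng_seed = NULL, sample_id = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ext <- c(spec$slices_per_volume, spec$in_plane_extent, spec$in_plane_extent)
  bg <- smooth_field(ext, spec$background_smoothness)
  bg <- 0.3 + 0.4 * (bg - min(bg)) / max(max(bg) - min(bg), 1e-12)
  vol <- bg
  mask <- array(0L, ext)
  if (stats::runif(1) < spec$lesion_probability) {
    les_range <- spec$lesions_per_volume
    n_les <- if (les_range[1L] == les_range[2L]) les_range[1L] else
      sample(seq(les_range[1L], les_range[2L]), 1L)
    coords <- cbind(rep(seq_len(ext[1L]), times = ext[2L] * ext[3L]),
                    rep(rep(seq_len(ext[2L]), each = ext[1L]), times = ext[3L]),
                    rep(seq_len(ext[3L]), each = ext[1L] * ext[2L]))
    for (l in seq_len(n_les)) {
      r <- stats::runif(3, spec$lesion_radius_range[1L], spec$lesion_radius_range[2L])
      ctr <- vapply(1:3, function(ax) {
        lo <- r[ax] + 1; hi <- ext[ax] - r[ax]
        if (hi <= lo) (ext[ax] + 1) / 2 else stats::runif(1, lo, hi)
      }, 0)
      rot <- qr.Q(qr(matrix(stats::rnorm(9), 3L)))
      m <- diag(1 / r) %*% t(rot)
      w <- sweep(coords, 2L, ctr) %*% t(m)
      q <- rowSums(w * w)
      pert <- spec$margin_irregularity * as.vector(smooth_field(ext, spec$background_smoothness / 2))
      inside <- q <= (1 + pert)^2
      mask[inside] <- 1L
    }
    vol[mask == 1L] <- bg[mask == 1L] * spec$lesion_contrast
  }
  vol <- vol + stats::rnorm(length(vol), sd = spec$noise_sd)
  dim(vol) <- ext
  volume_sample(vol, mask, sample_id = sample_id, voxel_spacing = spec$voxel_spacing)
}

#' Generate a phantom dataset with manifest
#'
#' Writes `n_volumes` image/mask NIfTI pairs plus a CSV manifest and a JSON
#' sidecar echoing the generator parameters.  With `metadata_only = TRUE`
#' only the manifest is produced (no voxel data), which scales to
#' paper-sized datasets where only the bookkeeping (e.g. the total 2-D slice
#' count) is of interest.  Fully reproducible from `spec$seed`; partial
#' output is removed if generation fails midway.
#'
#' @param spec A [phantom_spec()].
#' @param output_dir Directory to create/write into (ignored when
#'   `metadata_only`).
#' @param metadata_only Produce the manifest without generating voxel data.
#' @return A tibble manifest (`sample_id`, `image_path`, `mask_path`,
#'   `has_lesion`, `n_slices`) with attribute `total_slices =
#'   n_volumes * slices_per_volume`.
#' @export
generate_phantom_dataset <- function(spec, output_dir = NULL, metadata_only = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"))
  ids <- sprintf("phantom%03d", seq_len(spec$n_volumes))
  if (metadata_only) {
    man <- tibble::tibble(sample_id = ids, image_path = NA_character_,
                          mask_path = NA_character_, has_lesion = NA,
                          n_slices = spec$slices_per_volume)
    attr(man, "total_slices") <- spec$n_volumes * spec$slices_per_volume
    return(man)
  }
  if (is.null(output_dir)) stop("output_dir is required unless metadata_only = TRUE")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  written <- character(0)
  man <- tryCatch({
    rows <- lapply(seq_len(spec$n_volumes), function(i) {
      s <- generate_phantom_volume(spec, sample_id = ids[i])
      ip <- file.path(output_dir, paste0(ids[i], "_img.nii.gz"))
      mp <- file.path(output_dir, paste0(ids[i], "_mask.nii.gz"))
      write_volume(s$volume, ip, s$voxel_spacing)
      write_volume(s$mask, mp, s$voxel_spacing, mask = TRUE)
      written <<- c(written, ip, mp)
      tibble::tibble(sample_id = ids[i], image_path = ip, mask_path = mp,
                     has_lesion = s$has_lesion, n_slices = dim(s$volume)[1L])
    })
    dplyr::bind_rows(rows)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
  utils::write.csv(man, file.path(output_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(unclass(spec), file.path(output_dir, "phantom_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(man, "total_slices") <- spec$n_volumes * spec$slices_per_volume
  man
}

#' Load a generated phantom dataset into memory
#'
#' @param manifest Manifest tibble from [generate_phantom_dataset()] (or the
#'   path of a dataset directory containing `manifest.csv`).
#' @return A list of `volume_sample` objects.
#' @export
load_phantom_dataset <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(file.path(manifest, "manifest.csv"))
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    v <- read_volume(manifest$image_path[i])
    m <- read_volume(manifest$mask_path[i])
    volume_sample(v$volume, round(m$volume), sample_id = manifest$sample_id[i],
                  voxel_spacing = v$voxel_spacing)
  })
}
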