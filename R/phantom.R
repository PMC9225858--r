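#' Configuration for the synthetic abdominal phantom generator
#'
#' The generator emulates the statistical difficulties of axial abdominal CT
#' around the liver: one large irregular bright organ (the "liver"), a few
#' smaller nearby regions whose intensity distribution overlaps the liver's
#' (stand-ins for spleen / stomach / heart), optional darker internal
#' lesions, and additive acquisition noise. Intensities are in arbitrary
#' units in roughly [0, 1]; windowing and normalization belong to the
#' preprocessing step.
#'
#' @param image_size Pixels per side (square slices), >= 64 so that 32x32
#'   patches fit. Default 128 (test scale; clinical slices are 512).
#' @param n_slices Number of axial slices for [generate_volume()], >= 1.
#' @param liver_intensity_mean,liver_intensity_sd Mean and per-pixel
#'   standard deviation of the liver texture (arbitrary units).
#' @param confounder_count Number of similar-intensity neighboring regions.
#' @param confounder_intensity_offset Mean intensity offset of confounders
#'   relative to the liver; small values make the two pixel distributions
#'   overlap (0 makes them identical by construction).
#' @param lesion_probability Probability that a slice carries a darker
#'   internal lesion (still labeled liver in the ground truth).
#' @param noise_sd Standard deviation of additive Gaussian noise applied
#'   last.
#' @param background_intensity_mean Mean background intensity.
#' @param area_band Admissible liver area fraction per slice; generation
#'   retries until the mask lands inside this band.
#' @param seed Integer seed; all outputs are pure functions of
#'   (config, seed).
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 128L,
                           n_slices = 1L,
                           liver_intensity_mean = 0.55,
                           liver_intensity_sd = 0.06,
                           confounder_count = 3L,
                           confounder_intensity_offset = 0.03,
                           lesion_probability = 0,
                           noise_sd = 0.04,
                           background_intensity_mean = 0.25,
                           area_band = c(0.08, 0.45),
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 64L)
    stop("image_size must be >= 64 (twice the 32-pixel patch side)")
  if (n_slices < 1L) stop("n_slices must be >= 1")
  if (lesion_probability < 0 || lesion_probability > 1)
    stop("lesion_probability must lie in [0, 1]")
  if (confounder_count < 0L) stop("confounder_count must be >= 0")
  if (length(area_band) != 2L || area_band[1] >= area_band[2])
    stop("area_band must be (low, high) with low < high")
  structure(list(image_size = image_size, n_slices = as.integer(n_slices),
                 liver_intensity_mean = liver_intensity_mean,
                 liver_intensity_sd = liver_intensity_sd,
                 confounder_count = as.integer(confounder_count),
                 confounder_intensity_offset = confounder_intensity_offset,
                 lesion_probability = lesion_probability,
                 noise_sd = noise_sd,
                 background_intensity_mean = background_intensity_mean,
                 area_band = area_band, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Construct an image volume container
#'
#' A 2D slice or 3D stack of scalar intensities with voxel spacing metadata
#' and an optional paired binary mask (1 = liver).
#'
#' @param intensities Numeric matrix (H x W) or array (H x W x D).
#' @param spacing Physical units per voxel (informational).
#' @param mask Optional binary array of identical shape.
#' @param provenance Optional named list recording how the object was made.
#' @return An `image_volume`.
#' @export
image_volume <- function(intensities, spacing = c(1, 1, 1), mask = NULL,
                         provenance = list()) {
  if (!all(is.finite(intensities))) stop("intensities must be finite")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(intensities)))
      stop("mask shape must match intensities")
    if (!is_binary(mask)) stop("mask must contain only {0, 1}")
  }
  structure(list(intensities = intensities, spacing = spacing, mask = mask,
                 provenance = provenance),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<image_volume> %s%s\n", paste(d, collapse = " x "),
              if (is.null(x$mask)) "" else " (with mask)"))
  invisible(x)
}

# Base liver shape drawn deterministically from config$seed: an anisotropic
# ellipse with a low-order random Fourier perturbation of its boundary
# radius. Star-shaped by construction, hence a single connected component.
base_liver_shape <- function(config) {
  with_seed(derive_seed(config$seed, 0L), {
    S <- config$image_size
    target_frac <- mean(config$area_band) * 0.75   # aim below band center
    ab <- target_frac * S^2 / pi
    aspect <- stats::runif(1, 0.7, 1.4)
    a <- sqrt(ab * aspect); b <- ab / a
    list(cx = S * stats::runif(1, 0.42, 0.58),
         cy = S * stats::runif(1, 0.42, 0.58),
         a = a, b = b,
         m = 2:5,
         amp = stats::runif(4, 0, 0.10) / sqrt(2:5),
         phase = stats::runif(4, 0, 2 * pi))
  })
}

# Binary mask of a perturbed ellipse. `scale` multiplies the radius (used
# for the smooth cross-section profile along a volume); `jitter_amp` and
# `jitter_phase` add a slice-specific boundary ripple.
shape_mask <- function(shape, S, scale = 1, jitter_amp = NULL, jitter_phase = NULL) {
  x <- matrix(seq_len(S), S, S, byrow = TRUE) - shape$cx
  y <- matrix(seq_len(S), S, S) - shape$cy
  u <- x / shape$a
  v <- y / shape$b
  rho <- sqrt(u^2 + v^2)
  th <- atan2(v, u)
  r <- 1 + 0 * th
  for (i in seq_along(shape$m))
    r <- r + shape$amp[i] * cos(shape$m[i] * th + shape$phase[i])
  if (!is.null(jitter_amp))
    for (i in seq_along(jitter_amp))
      r <- r + jitter_amp[i] * cos((i + 1) * th + jitter_phase[i])
  (rho <= scale * pmax(r, 0.05)) * 1L
}

# One confounder blob (small perturbed ellipse) that must not touch the
# liver mask; placed by rejection sampling, dropped after `tries` failures.
place_confounder <- function(liver, S, tries = 60L) {
  for (t in seq_len(tries)) {
    rad <- stats::runif(1, 0.045, 0.10) * S
    sh <- list(cx = stats::runif(1, rad + 2, S - rad - 2),
               cy = stats::runif(1, rad + 2, S - rad - 2),
               a = rad * stats::runif(1, 0.8, 1.25), b = rad,
               m = 2:3, amp = stats::runif(2, 0, 0.15), phase = stats::runif(2, 0, 2 * pi))
    m <- shape_mask(sh, S)
    if (!any(m & liver) && sum(m) > 0) return(m)
  }
  NULL
}

generate_slice_impl <- function(config, slice_seed, scale = 1) {
  S <- config$image_size
  shape <- base_liver_shape(config)
  with_seed(slice_seed, {
    mask <- NULL
    for (try in seq_len(25L)) {
      jitter_amp <- stats::runif(3, 0, 0.02)
      jitter_phase <- stats::runif(3, 0, 2 * pi)
      m <- shape_mask(shape, S, scale = scale,
                      jitter_amp = jitter_amp, jitter_phase = jitter_phase)
      frac <- mean(m)
      if (frac >= config$area_band[1] && frac <= config$area_band[2]) {
        mask <- m
        break
      }
    }
    if (is.null(mask))
      stop("could not generate a liver mask inside the configured area band")

    img <- matrix(config$background_intensity_mean, S, S)
    liver_tex <- config$liver_intensity_mean +
      if (config$liver_intensity_sd > 0)
        stats::rnorm(sum(mask), 0, config$liver_intensity_sd) else 0
    img[mask == 1] <- liver_tex

    conf <- matrix(0L, S, S)
    if (config$confounder_count > 0) {
      for (i in seq_len(config$confounder_count)) {
        cm <- place_confounder(mask, S)
        if (is.null(cm)) next
        tex <- config$liver_intensity_mean + config$confounder_intensity_offset +
          if (config$liver_intensity_sd > 0)
            stats::rnorm(sum(cm), 0, config$liver_intensity_sd) else 0
        img[cm == 1] <- tex
        conf <- conf | cm
      }
    }

    if (config$lesion_probability > 0 &&
        stats::runif(1) < config$lesion_probability) {
      # a darker disk inside the liver; ground truth still labels it liver
      inside <- which(mask == 1, arr.ind = TRUE)
      ctr <- inside[sample.int(nrow(inside), 1L), ]
      rad <- stats::runif(1, 0.02, 0.05) * S
      les <- shape_mask(list(cx = ctr[2], cy = ctr[1], a = rad, b = rad,
                             m = 2L, amp = 0.1, phase = 0), S) & mask
      img[les] <- img[les] - 0.15
    }

    if (config$noise_sd > 0)
      img <- img + stats::rnorm(S * S, 0, config$noise_sd)

    image_volume(img, mask = mask * 1,
                 provenance = list(kind = "synthetic_phantom",
                                   slice_seed = slice_seed,
                                   config_seed = config$seed,
                                   confounder_pixels = sum(conf)))
  })
}

#' Generate one synthetic axial phantom slice with its ground-truth mask
#'
#' The liver is a single connected, irregularly shaped bright region (an
#' ellipse with a random low-order Fourier boundary perturbation, drawn
#' deterministically from `config$seed`); confounder regions with
#' overlapping intensities are placed outside it by rejection sampling;
#' additive Gaussian noise is applied last. Bit-identical output for equal
#' `(config, slice_seed)`.
#'
#' @param config A [phantom_config()].
#' @param slice_seed Integer seed for the slice-specific randomness
#'   (boundary ripple, textures, confounder placement, noise).
#' @return An [image_volume()] with a 2D intensity matrix and binary mask.
#' @export
generate_slice <- function(config, slice_seed = derive_seed(config$seed, 1L)) {
  stopifnot(inherits(config, "phantom_config"))
  generate_slice_impl(config, slice_seed)
}

#' Generate a synthetic phantom volume
#'
#' Stacks [generate_slice()] outputs with per-slice seeds derived
#' deterministically from `config$seed`. The liver cross-section follows a
#' smooth scaling profile along the stack so adjacent masks overlap
#' strongly, as liver cross-sections do across neighboring axial slices.
#'
#' @param config A [phantom_config()] with `n_slices >= 1`.
#' @return An [image_volume()] with H x W x n_slices intensities and mask.
#' @export
generate_volume <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n_slices
  u <- if (n == 1L) 0 else (seq_len(n) - (n + 1) / 2) / ((n + 1) / 2)
  scale <- sqrt(1 - 0.35 * u^2)
  slices <- lapply(seq_len(n), function(i)
    generate_slice_impl(config, derive_seed(config$seed, i), scale = scale[i]))
  S <- config$image_size
  img <- array(NA_real_, c(S, S, n))
  msk <- array(NA_real_, c(S, S, n))
  for (i in seq_len(n)) {
    img[, , i] <- slices[[i]]$intensities
    msk[, , i] <- slices[[i]]$mask
  }
  image_volume(img, mask = msk,
               provenance = list(kind = "synthetic_phantom_volume",
                                 config_seed = config$seed, n_slices = n))
}

#' Write a set of phantom volumes as NIfTI fixtures with a manifest
#'
#' Writes `image_###.nii.gz` / `mask_###.nii.gz` pairs plus a
#' `manifest.json` listing files, per-volume seeds and a hash of the
#' generating configuration. All data are synthetic.
#'
#' @param config A [phantom_config()]; volume `i` uses seed
#'   `derive_seed(config$seed, 1000 + i)`.
#' @param n_volumes Number of volumes (>= 0).
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly (also written as JSON).
#' @export
write_fixture_set <- function(config, n_volumes, out_dir) {
  stopifnot(inherits(config, "phantom_config"), n_volumes >= 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile(fileext = ".json"); writeLines(cfg_json, tf)
  cfg_hash <- unname(tools::md5sum(tf)); unlink(tf)
  entries <- vector("list", n_volumes)
  for (i in seq_len(n_volumes)) {
    vseed <- derive_seed(config$seed, 1000L + i)
    vcfg <- config; vcfg$seed <- vseed
    vol <- generate_volume(vcfg)
    img_file <- sprintf("image_%03d.nii.gz", i)
    msk_file <- sprintf("mask_%03d.nii.gz", i)
    RNifti::writeNifti(RNifti::asNifti(vol$intensities, datatype = "double"),
                       file.path(out_dir, img_file))
    RNifti::writeNifti(RNifti::asNifti(vol$mask, datatype = "uint8"),
                       file.path(out_dir, msk_file))
    entries[[i]] <- list(image = img_file, mask = msk_file, seed = vseed)
  }
  manifest <- list(config_hash = cfg_hash, config = unclass(config),
                   n_volumes = n_volumes, volumes = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
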