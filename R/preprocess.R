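#' Preprocessing configuration
#'
#' Slice preprocessing is intensity windowing (contrast control), z-scoring
#' and rescaling to [0, 1]; training-time augmentation is right-angle
#' rotation of image/mask pairs.
#'
#' @param window_low,window_high Clipping bounds in intensity units
#'   (defaults wide open, appropriate for phantom data already in [0, 1];
#'   clinical CT would use a liver window in Hounsfield units).
#' @param rotations Right-angle rotation degrees applied during
#'   augmentation, a subset of c(90, 180, 270).
#' @param crop_mode `"none"` or `"body_bbox"` (crop to the bounding box of
#'   above-background content while always retaining the full liver mask).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_low = -Inf, window_high = Inf,
                              rotations = c(90, 180, 270),
                              crop_mode = c("none", "body_bbox")) {
  if (window_low >= window_high) stop("window_low must be < window_high")
  if (!all(rotations %in% c(90, 180, 270)))
    stop("rotations must be a subset of c(90, 180, 270)")
  structure(list(window_low = window_low, window_high = window_high,
                 rotations = rotations, crop_mode = match.arg(crop_mode)),
            class = "preprocess_config")
}

#' Normalize one slice to [0, 1]
#'
#' Clips intensities to the configured window, standardizes to zero mean and
#' unit variance, then affinely rescales so the minimum maps to 0 and the
#' maximum to 1. A constant slice (zero variance) maps to all zeros.
#'
#' @param slice Numeric matrix of finite intensities.
#' @param config A [preprocess_config()].
#' @return A matrix of the same shape with values in [0, 1].
#' @export
normalize_slice <- function(slice, config = preprocess_config()) {
  if (length(slice) == 0L) stop("empty slice")
  if (!all(is.finite(slice))) stop("slice must be finite")
  x <- pmin(pmax(slice, config$window_low), config$window_high)
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(array(0, dim(slice) %||% length(slice)))
  z <- (x - mean(x)) / s
  (z - min(z)) / (max(z) - min(z))
}

#' Right-angle rotation augmentation of an image/mask pair
#'
#' Returns the original pair plus one identically rotated copy per
#' configured angle (defaults 90, 180, 270 degrees: four pairs in total).
#' Augmentation is a training-time operation; inference uses unaugmented
#' slices.
#'
#' @param image,mask Numeric matrices of identical shape.
#' @param config A [preprocess_config()].
#' @return A list of `list(image =, mask =)` pairs.
#' @export
augment <- function(image, mask, config = preprocess_config()) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  out <- list(list(image = image, mask = mask))
  for (deg in config$rotations) {
    k <- deg %/% 90L
    out[[length(out) + 1L]] <- list(image = rot90(image, k), mask = rot90(mask, k))
  }
  out
}

#' Crop an image/mask pair to the body bounding box
#'
#' Crops both arrays to the bounding box of above-background content
#' (intensities above `min + 10%` of the dynamic range), expanded to always
#' contain the full liver mask with a margin of at least 16 pixels where the
#' frame allows. A constant (all-background) image is returned unchanged.
#'
#' @param image Numeric matrix.
#' @param mask Binary matrix of the same shape.
#' @param margin Margin in pixels kept around the union box (default 16).
#' @return `list(image =, mask =)` cropped identically.
#' @export
crop_body <- function(image, mask, margin = 16L) {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (!is_binary(mask)) stop("mask must be binary")
  rng <- range(image)
  if (diff(rng) == 0) return(list(image = image, mask = mask))
  content <- image > rng[1] + 0.1 * diff(rng)
  content <- content | (mask == 1)
  rows <- which(rowSums(content) > 0)
  cols <- which(colSums(content) > 0)
  r0 <- max(1L, min(rows) - margin); r1 <- min(nrow(image), max(rows) + margin)
  c0 <- max(1L, min(cols) - margin); c1 <- min(ncol(image), max(cols) + margin)
  list(image = image[r0:r1, c0:c1, drop = FALSE],
       mask = mask[r0:r1, c0:c1, drop = FALSE])
}
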