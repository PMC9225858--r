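#' An oracle patch classifier for pipeline round-trip checks
#'
#' A stub standing in for a trained network: it "classifies" each patch by
#' returning the ground-truth mask value at the patch center. Pushing it
#' through the dense-inference pipeline at stride 1 must reproduce the mask
#' exactly, which isolates the plumbing (patch extraction, coordinate
#' conventions, map assembly) from the learning.
#'
#' @param mask Binary ground-truth matrix for the slice to be "segmented".
#' @return An `oracle_classifier`.
#' @export
oracle_classifier <- function(mask) {
  stopifnot(is_binary(mask))
  structure(list(mask = mask), class = "oracle_classifier")
}

center_probs <- function(model, slice, centers) {
  UseMethod("center_probs")
}

#' @export
center_probs.gacnn <- function(model, slice, centers) {
  x <- extract_patches_at(slice, centers, model$spec$input_shape[["side"]])
  forward(model, x)[, 2]
}

#' @export
center_probs.oracle_classifier <- function(model, slice, centers) {
  if (!identical(dim(model$mask), dim(slice)))
    stop("oracle mask shape does not match the slice")
  model$mask[(centers[, 2] - 1L) * nrow(slice) + centers[, 1]]
}

#' Dense liver-probability map for one slice
#'
#' Evaluates the classifier on the patch around every [inference_grid()]
#' center (patches served with reflection padding at borders) and writes
#' the liver-class softmax probability to that pixel. With `stride > 1`
#' intervening pixels receive the probability of their nearest center.
#'
#' @param model A `gacnn` in eval mode, or an [oracle_classifier()].
#' @param slice Numeric matrix normalized to [0, 1].
#' @param stride Lattice stride (default 1: one prediction per pixel).
#' @param strict Error (instead of warn + clip) on values outside [0, 1].
#' @param source_id Identifier recorded on the map.
#' @return A `probability_map` with `$values` in [0, 1] of the slice shape.
#' @export
probability_map <- function(model, slice, stride = 1L, strict = FALSE,
                            source_id = "slice") {
  tol <- 1e-8
  if (min(slice) < -tol || max(slice) > 1 + tol) {
    if (strict) stop("slice is not normalized to [0, 1]")
    warning("slice values outside [0, 1]; clipping")
    slice <- pmin(pmax(slice, 0), 1)
  }
  if (inherits(model, "gacnn") && !identical(model$mode, "eval"))
    stop("model must be in eval mode for inference")
  centers <- inference_grid(dim(slice), stride)
  p <- center_probs(model, slice, centers)
  values <- matrix(NA_real_, nrow(slice), ncol(slice))
  values[(centers[, 2] - 1L) * nrow(slice) + centers[, 1]] <- p
  if (stride > 1L) {
    near <- function(n) {
      lattice <- seq(1L, n, by = stride)
      pmin(round((seq_len(n) - 1L) / stride) * stride + 1L, lattice[length(lattice)])
    }
    values <- values[near(nrow(slice)), near(ncol(slice)), drop = FALSE]
  }
  structure(list(values = values, source_id = source_id, stride = as.integer(stride)),
            class = "probability_map")
}

#' Threshold a probability map into a binary mask
#'
#' Pixels with probability greater than or equal to the threshold become
#' liver (ties go to liver).
#'
#' @param map A `probability_map` (or plain matrix in [0, 1]).
#' @param threshold Scalar in (0, 1); default 0.5.
#' @param strict_greater Use strict `>` instead of `>=` (used by
#'   complementarity checks).
#' @return A `segmentation_mask` with binary `$values`.
#' @export
binarize <- function(map, threshold = 0.5, strict_greater = FALSE) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  v <- if (inherits(map, "probability_map")) map$values else map
  values <- if (strict_greater) (v > threshold) * 1 else (v >= threshold) * 1
  structure(list(values = values,
                 provenance = list(threshold = threshold,
                                   stride = if (inherits(map, "probability_map"))
                                     map$stride else NA_integer_)),
            class = "segmentation_mask")
}

#' Median (majority-vote) smoothing of a binary mask
#'
#' The median of a binary neighborhood is its majority value, so the
#' window x window median filter is computed exactly as a majority vote
#' over the reflection-padded neighborhood of each pixel. Odd windows make
#' ties impossible. The published post-processing uses a 5 x 5 window.
#'
#' @param mask A `segmentation_mask` or binary matrix.
#' @param window Odd window side (default 5); 1 is the identity.
#' @return Same type as the input, smoothed.
#' @export
median_smooth <- function(mask, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  v <- if (inherits(mask, "segmentation_mask")) mask$values else mask
  if (!is_binary(v)) stop("mask must be binary")
  if (window > 1L) {
    h <- window %/% 2L
    p <- reflect_pad(v, h)
    # box sums via a 2D summed-area table
    sat <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed SAT
    sat <- t(sat)
    sat <- rbind(0, cbind(0, sat))
    H <- nrow(v); W <- ncol(v)
    r0 <- 1:H; r1 <- r0 + window; c0 <- 1:W; c1 <- c0 + window
    counts <- sat[r1, c1, drop = FALSE] - sat[r0, c1, drop = FALSE] -
      sat[r1, c0, drop = FALSE] + sat[r0, c0, drop = FALSE]
    v <- (counts > window^2 / 2) * 1
  }
  if (inherits(mask, "segmentation_mask")) {
    mask$values <- v
    mask$provenance$median_window <- window
    mask
  } else v
}

#' Segment a volume slice by slice
#'
#' Applies normalize -> probability map -> binarize -> median smoothing
#' independently to every axial slice and stacks the results.
#'
#' @param model A `gacnn` in eval mode or an [oracle_classifier()] (the
#'   oracle uses the volume's own mask per slice).
#' @param volume An [image_volume()].
#' @param threshold Binarization threshold.
#' @param stride Inference lattice stride.
#' @param median_window Median filter window (1 disables smoothing).
#' @param preprocess A [preprocess_config()] for normalization.
#' @return An [image_volume()] whose `$mask` is the predicted segmentation
#'   and whose provenance records threshold, stride and window.
#' @export
segment_volume <- function(model, volume, threshold = 0.5, stride = 1L,
                           median_window = 5L, preprocess = preprocess_config()) {
  stopifnot(inherits(volume, "image_volume"))
  d <- dim(volume$intensities)
  n_slices <- if (length(d) == 3L) d[3] else 1L
  get_slice <- function(i) if (length(d) == 3L) volume$intensities[, , i] else volume$intensities
  out <- array(NA_real_, c(d[1], d[2], n_slices))
  for (i in seq_len(n_slices)) {
    res <- tryCatch({
      sl <- normalize_slice(get_slice(i), preprocess)
      m <- if (inherits(model, "oracle_classifier")) {
        truth <- if (length(d) == 3L) volume$mask[, , i] else volume$mask
        oracle_classifier(truth)
      } else model
      pm <- probability_map(m, sl, stride = stride,
                            source_id = sprintf("slice_%03d", i))
      sm <- binarize(pm, threshold)
      median_smooth(sm, median_window)
    }, error = function(e) stop(sprintf("slice %d: %s", i, conditionMessage(e)),
                                call. = FALSE))
    out[, , i] <- res$values
  }
  if (length(d) == 2L) out <- out[, , 1]
  image_volume(volume$intensities, spacing = volume$spacing, mask = out,
               provenance = c(volume$provenance,
                              list(segmentation = list(threshold = threshold,
                                                       stride = stride,
                                                       median_window = median_window))))
}
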