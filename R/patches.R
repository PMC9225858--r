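#' The class label of a patch centered at a pixel
#'
#' A patch inherits the ground-truth mask value at its center pixel, the
#' convention under which training labels and per-pixel reconstruction
#' semantics coincide.
#'
#' @param mask Binary matrix.
#' @param center `(row, col)` coordinate (1-based) inside the mask.
#' @return 0 or 1.
#' @export
label_at <- function(mask, center) {
  r <- center[1]; c <- center[2]
  if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask))
    stop(sprintf("center (%d, %d) outside a %d x %d mask", r, c, nrow(mask), ncol(mask)))
  mask[r, c]
}

#' Cut one fixed-size patch around a center pixel
#'
#' With half-width `h = side/2`, the patch covers rows
#' `[r - h, r + h)` and columns `[c - h, c + h)` in 0-based half-open
#' convention (so the center sits at 0-based offset `h` inside the patch,
#' and a 32x32 image with 0-based center (16, 16) yields the whole image).
#' Out-of-bounds pixels are filled by symmetric reflection, or zeros when
#' `pad = "zero"`.
#'
#' @param image Numeric matrix.
#' @param center `(row, col)`, 1-based.
#' @param side Patch side (default 32).
#' @param pad `"reflect"` (default) or `"zero"`.
#' @return A `side` x `side` matrix.
#' @export
cut_patch <- function(image, center, side = 32L, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  h <- side %/% 2L
  rows <- (center[1] - h):(center[1] + h - 1L)
  cols <- (center[2] - h):(center[2] + h - 1L)
  if (pad == "reflect") {
    image[reflect_index(rows, nrow(image)), reflect_index(cols, ncol(image)),
          drop = FALSE]
  } else {
    out <- matrix(0, side, side)
    rok <- rows >= 1L & rows <= nrow(image)
    cok <- cols >= 1L & cols <= ncol(image)
    out[rok, cok] <- image[rows[rok], cols[cok], drop = FALSE]
    out
  }
}

new_patch_set <- function(x, labels, centers, source_ids, side = 32L) {
  structure(list(x = x, labels = labels, centers = centers,
                 source_ids = source_ids, side = side),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches (%d x %d), %d liver / %d background\n",
              ncol(x$x), x$side, x$side, sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' Patches of a patch set as a 4D array
#'
#' @param ps A `patch_set`.
#' @return Array of shape (side, side, 1, N): single-channel patches.
#' @export
patch_array <- function(ps) {
  stopifnot(inherits(ps, "patch_set"))
  array(ps$x, c(ps$side, ps$side, 1L, ncol(ps$x)))
}

#' Combine patch sets
#'
#' @param ... `patch_set` objects with equal patch side.
#' @return One `patch_set`.
#' @export
bind_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) > 0, all(vapply(sets, inherits, TRUE, "patch_set")))
  side <- unique(vapply(sets, `[[`, 1L, "side"))
  stopifnot(length(side) == 1L)
  new_patch_set(do.call(cbind, lapply(sets, `[[`, "x")),
                unlist(lapply(sets, `[[`, "labels")),
                do.call(rbind, lapply(sets, `[[`, "centers")),
                unlist(lapply(sets, `[[`, "source_ids")), side)
}

# Vectorized extraction of many patches from one slice: pad once by
# reflection, then gather one offset at a time across all centers.
extract_patches_at <- function(image, centers, side = 32L) {
  h <- side %/% 2L
  padded <- reflect_pad(image, h)
  H <- nrow(padded)
  n <- nrow(centers)
  x <- matrix(NA_real_, side * side, n)
  base_r <- centers[, 1]          # padded row of patch start = center - h + h
  base_c <- centers[, 2]
  for (dc in 0:(side - 1L)) {
    cols <- base_c + dc
    for (dr in 0:(side - 1L)) {
      x[dr + side * dc + 1L, ] <- padded[(cols - 1L) * H + base_r + dr]
    }
  }
  x
}

#' Extract class-balanced labeled training patches from one slice
#'
#' Samples `n_per_class` centers uniformly without replacement from liver
#' pixels and the same number from background pixels, then cuts the 32x32
#' patch around each. By default centers must be at least `side/2` pixels
#' from every border; with `allow_border = TRUE` any pixel is eligible and
#' border patches are served via reflection padding.
#'
#' @param image Numeric matrix (normalized slice).
#' @param mask Binary matrix of the same shape.
#' @param n_per_class Patches per class, >= 1.
#' @param seed Integer seed; equal seeds give identical patch sets.
#' @param side Patch side (default 32).
#' @param allow_border Allow centers closer than `side/2` to a border.
#' @param source_id Identifier stored with each patch.
#' @return A `patch_set` with `2 * n_per_class` patches, labels exactly
#'   balanced.
#' @export
extract_balanced <- function(image, mask, n_per_class, seed = 1L, side = 32L,
                             allow_border = FALSE, source_id = "slice") {
  if (!identical(dim(image), dim(mask))) stop("image and mask shapes differ")
  if (!is_binary(mask)) stop("mask must be binary")
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  h <- side %/% 2L
  eligible <- matrix(TRUE, nrow(image), ncol(image))
  if (!allow_border) {
    eligible[] <- FALSE
    if (nrow(image) >= side && ncol(image) >= side)
      eligible[(h + 1L):(nrow(image) - h), (h + 1L):(ncol(image) - h)] <- TRUE
  }
  pos <- which(eligible & mask == 1)
  neg <- which(eligible & mask == 0)
  if (length(pos) < n_per_class)
    stop(sprintf("only %d eligible liver pixels for %d requested patches",
                 length(pos), n_per_class))
  if (length(neg) < n_per_class)
    stop(sprintf("only %d eligible background pixels for %d requested patches",
                 length(neg), n_per_class))
  idx <- with_seed(seed, c(sample(pos, n_per_class), sample(neg, n_per_class)))
  centers <- cbind(row = (idx - 1L) %% nrow(image) + 1L,
                   col = (idx - 1L) %/% nrow(image) + 1L)
  labels <- c(rep(1L, n_per_class), rep(0L, n_per_class))
  x <- extract_patches_at(image, centers, side)
  new_patch_set(x, labels, centers, rep(source_id, 2L * n_per_class), side)
}

#' Regular lattice of inference centers covering a slice
#'
#' Centers are placed every `stride` pixels starting at the first pixel, so
#' stride 1 yields one center per pixel and every pixel has a nearest
#' lattice point within `stride/2`.
#'
#' @param image_shape `(H, W)`.
#' @param stride Integer >= 1.
#' @return Matrix of `(row, col)` centers (1-based), row-fastest.
#' @export
inference_grid <- function(image_shape, stride = 1L) {
  if (stride < 1L) stop("stride must be >= 1")
  rows <- seq(1L, image_shape[1], by = stride)
  cols <- seq(1L, image_shape[2], by = stride)
  cbind(row = rep(rows, times = length(cols)),
        col = rep(cols, each = length(rows)))
}
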