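#' Declare one network layer
#'
#' A layer is described the way architecture tables in the segmentation
#' literature describe them: kind, kernel side, stride, padding and the
#' output depth (channels for convolutions, units for fully connected
#' layers). Pooling and softmax layers carry no trainable parameters.
#'
#' @param kind One of `"conv"`, `"maxpool"`, `"fc"`, `"softmax"`.
#' @param kernel Integer kernel side (>= 1); ignored for softmax.
#' @param stride Integer stride (>= 1).
#' @param padding Integer zero-padding (>= 0).
#' @param out Output channels (conv) or units (fc); `NA` otherwise.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, kernel = 1L, stride = 1L, padding = 0L, out = NA_integer_) {
  kind <- match.arg(kind, c("conv", "maxpool", "fc", "softmax"))
  kernel <- as.integer(kernel); stride <- as.integer(stride); padding <- as.integer(padding)
  if (kind != "softmax") {
    if (kernel < 1L || stride < 1L) stop("kernel and stride must be >= 1")
    if (padding < 0L) stop("padding must be >= 0")
  }
  structure(list(kind = kind, kernel = kernel, stride = stride,
                 padding = padding, out = as.integer(out)),
            class = "layer_spec")
}

#' LRN hyperparameters
#'
#' Cross-channel local response normalization divides each activation by
#' `(k + alpha * sum of squared activations over n neighboring channels)^beta`.
#' Defaults are the standard values of the convention this layer was
#' popularized with: k = 2, n = 5, alpha = 1e-4, beta = 0.75.
#'
#' @param k Additive constant, >= 0.
#' @param alpha Scale of the squared-energy term, >= 0.
#' @param beta Exponent, > 0.
#' @param n Channel neighborhood size, >= 1.
#' @return An `lrn_params` list.
#' @export
lrn_params <- function(k = 2, alpha = 1e-4, beta = 0.75, n = 5L) {
  if (k < 0 || alpha < 0 || beta <= 0 || n < 1) stop("invalid LRN hyperparameters")
  structure(list(k = k, alpha = alpha, beta = beta, n = as.integer(n)),
            class = "lrn_params")
}

#' The default patch-classification network specification
#'
#' Three convolution blocks (conv -> ReLU -> LRN -> max-pool) followed by a
#' 4096-unit fully connected layer with dropout, a 2-unit fully connected
#' layer and a softmax over \{background, liver\}. The first pooling layer
#' uses stride 1 with padding 1 so that the 13x13 map of the first
#' convolution is preserved; the later pools halve the map (13 -> 6 -> 3),
#' giving the 3*3*256 = 2304 features entering the first fully connected
#' layer. Input patches are 1 x 32 x 32.
#'
#' @param dropout_rate Dropout probability after the first fully connected
#'   layer (train mode only). Default 0.3.
#' @param lrn [lrn_params()] applied after each convolution's ReLU.
#' @param input_side Patch side in pixels (default 32).
#' @return A `network_spec` object.
#' @export
gacnn_spec <- function(dropout_rate = 0.3, lrn = lrn_params(), input_side = 32L) {
  layers <- list(
    conv1 = layer_spec("conv",    7L, 2L, 0L, 32L),
    pool1 = layer_spec("maxpool", 3L, 1L, 1L),
    conv2 = layer_spec("conv",    5L, 1L, 2L, 192L),
    pool2 = layer_spec("maxpool", 3L, 2L, 0L),
    conv3 = layer_spec("conv",    3L, 1L, 1L, 256L),
    pool3 = layer_spec("maxpool", 2L, 2L, 0L),
    fc1   = layer_spec("fc", out = 4096L),
    fc2   = layer_spec("fc", out = 2L),
    softmax = layer_spec("softmax")
  )
  structure(list(input_shape = c(channels = 1L, side = as.integer(input_side),
                                 side = as.integer(input_side)),
                 layers = layers, dropout_rate = dropout_rate, lrn = lrn),
            class = "network_spec")
}

#' Spatial output side of a conv or pooling layer
#'
#' `floor((input_side + 2*padding - kernel) / stride) + 1`, the floor
#' convention under which a 7/2/0 convolution maps a 32-pixel side to 13.
#'
#' @param layer A [layer_spec()].
#' @param input_side Integer input side.
#' @return Integer output side.
#' @export
output_shape <- function(layer, input_side) {
  stopifnot(inherits(layer, "layer_spec"))
  if (!layer$kind %in% c("conv", "maxpool")) return(1L)
  num <- input_side + 2L * layer$padding - layer$kernel
  if (num < 0L)
    stop(sprintf("layer (kernel %d, pad %d) larger than its %d-pixel input",
                 layer$kernel, layer$padding, input_side))
  num %/% layer$stride + 1L
}

#' Propagate the spatial shape and depth chain through a network spec
#'
#' @param spec A [gacnn_spec()]-style `network_spec`.
#' @return A data frame with one row per layer: name, kind, output side and
#'   depth.
#' @export
spec_shapes <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  side <- spec$input_shape[["side"]]
  depth <- spec$input_shape[["channels"]]
  rows <- lapply(seq_along(spec$layers), function(i) {
    l <- spec$layers[[i]]
    if (l$kind %in% c("conv", "maxpool")) {
      side <<- output_shape(l, side)
      if (l$kind == "conv") depth <<- l$out
    } else if (l$kind == "fc") {
      side <<- 1L
      depth <<- l$out
    }
    data.frame(layer = names(spec$layers)[i], kind = l$kind,
               side = side, depth = depth)
  })
  do.call(rbind, rows)
}

#' Per-layer and total trainable parameter counts
#'
#' Convolutions contribute `k^2 * in_channels * out_channels + out_channels`,
#' fully connected layers `in_units * out_units + out_units`; pooling and
#' softmax layers contribute nothing.
#'
#' @param spec A `network_spec`.
#' @return A data frame (layer, kind, params) with the grand total in
#'   `attr(, "total")`.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  side <- spec$input_shape[["side"]]
  depth <- spec$input_shape[["channels"]]
  params <- integer(length(spec$layers))
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    if (l$kind == "conv") {
      params[i] <- as.integer(l$kernel^2 * depth * l$out + l$out)
      side <- output_shape(l, side)
      depth <- l$out
    } else if (l$kind == "maxpool") {
      side <- output_shape(l, side)
    } else if (l$kind == "fc") {
      in_units <- side^2 * depth
      params[i] <- as.integer(in_units * l$out + l$out)
      side <- 1L
      depth <- l$out
    }
  }
  out <- data.frame(layer = names(spec$layers),
                    kind = vapply(spec$layers, `[[`, "", "kind"),
                    params = params, row.names = NULL)
  attr(out, "total") <- as.integer(sum(params))
  out
}

#' Local response normalization
#'
#' Normalizes each activation by the squared-activation energy of its
#' cross-channel neighborhood:
#' `b[i] = a[i] / (k + alpha * sum_{j = max(0, i - n/2)}^{min(C-1, i + n/2)} a[j]^2)^beta`
#' (0-based channel indices; the window is truncated at the channel
#' boundaries). Accepts an H x W x C array or a plain channel vector.
#'
#' @param activations Numeric array (H, W, C) or numeric vector (one value
#'   per channel).
#' @param params [lrn_params()].
#' @return Same shape as the input.
#' @export
lrn <- function(activations, params = lrn_params()) {
  stopifnot(inherits(params, "lrn_params"), all(is.finite(activations)))
  a <- activations
  vec_in <- is.null(dim(a))
  if (vec_in) dim(a) <- c(1L, 1L, length(a))
  if (length(dim(a)) != 3L) stop("activations must be H x W x C (or a channel vector)")
  d <- dim(a)
  C <- d[3]
  half <- params$n %/% 2L
  sq <- a^2
  # cumulative energy along the channel axis, then truncated-window sums
  if (C == 1L) {
    win <- sq
  } else {
    cum <- apply(sq, c(1, 2), cumsum)          # C x H x W
    cum <- aperm(cum, c(2, 3, 1))              # H x W x C
    win <- array(0, d)
    for (i in seq_len(C)) {
      lo <- max(1L, i - half); hi <- min(C, i + half)
      win[, , i] <- cum[, , hi] - if (lo > 1L) cum[, , lo - 1L] else 0
    }
  }
  out <- a / (params$k + params$alpha * win)^params$beta
  if (vec_in) dim(out) <- NULL
  out
}

geom_matrix <- function(spec) {
  conv_pool <- Filter(function(l) l$kind %in% c("conv", "maxpool"), spec$layers)
  m <- t(vapply(conv_pool, function(l) c(l$kernel, l$stride, l$padding), integer(3)))
  storage.mode(m) <- "integer"
  m
}

param_shapes <- function(spec) {
  side <- spec$input_shape[["side"]]
  depth <- spec$input_shape[["channels"]]
  shapes <- list()
  ci <- 0L; fi <- 0L
  for (l in spec$layers) {
    if (l$kind == "conv") {
      ci <- ci + 1L
      shapes[[paste0("W", ci)]] <- c(l$out, l$kernel^2 * depth)
      shapes[[paste0("b", ci)]] <- l$out
      side <- output_shape(l, side)
      depth <- l$out
    } else if (l$kind == "maxpool") {
      side <- output_shape(l, side)
    } else if (l$kind == "fc") {
      fi <- fi + 1L
      idx <- ci + fi
      shapes[[paste0("W", idx)]] <- c(l$out, side^2 * depth)
      shapes[[paste0("b", idx)]] <- l$out
      side <- 1L
      depth <- l$out
    }
  }
  shapes
}

new_gacnn <- function(spec, params, mode = "eval", init = "gaussian", sigma = NA_real_,
                      seed = NA_integer_) {
  structure(list(spec = spec, params = params, mode = mode,
                 init = init, sigma = sigma, seed = seed, epoch = 0L),
            class = "gacnn")
}

#' Initialize the network with i.i.d. Gaussian weights
#'
#' Every weight is drawn from a zero-mean Gaussian with standard deviation
#' `sigma`; all biases start at zero. The published training recipe uses
#' `sigma = 1e-4`; see the methods vignette for an analysis of what that
#' scale implies for trainability of a five-layer network.
#'
#' @param spec A `network_spec`.
#' @param sigma Weight standard deviation, > 0. Default 1e-4.
#' @param seed Integer RNG seed; the same seed reproduces the same model.
#' @return A `gacnn` model in eval mode.
#' @export
init_gaussian <- function(spec = gacnn_spec(), sigma = 1e-4, seed = 1L) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  shapes <- param_shapes(spec)
  params <- with_seed(seed, lapply(shapes, function(s) {
    if (length(s) == 2L) matrix(stats::rnorm(prod(s), 0, sigma), s[1], s[2])
    else numeric(s)  # biases zero
  }))
  new_gacnn(spec, params, init = "gaussian", sigma = sigma, seed = as.integer(seed))
}

#' Initialize the network with fan-in-scaled (He) Gaussian weights
#'
#' Per-layer standard deviation `sqrt(2 / fan_in)`, the standard scale for
#' ReLU networks that keeps activation magnitudes of order one through
#' depth. Provided alongside [init_gaussian()] so the effect of the
#' initialization scale on trainability can be studied directly.
#'
#' @inheritParams init_gaussian
#' @return A `gacnn` model in eval mode.
#' @export
init_he <- function(spec = gacnn_spec(), seed = 1L) {
  shapes <- param_shapes(spec)
  params <- with_seed(seed, lapply(shapes, function(s) {
    if (length(s) == 2L) matrix(stats::rnorm(prod(s), 0, sqrt(2 / s[2])), s[1], s[2])
    else numeric(s)
  }))
  new_gacnn(spec, params, init = "he", seed = as.integer(seed))
}

#' Switch a model between train and eval mode
#'
#' Dropout is applied stochastically in train mode and disabled (with
#' inverted scaling at train time, so no rescale is needed) in eval mode.
#'
#' @param model A `gacnn`.
#' @param mode `"train"` or `"eval"`.
#' @return The model with the requested mode.
#' @export
set_mode <- function(model, mode = c("eval", "train")) {
  stopifnot(inherits(model, "gacnn"))
  model$mode <- match.arg(mode)
  model
}

as_patch_matrix <- function(batch, side) {
  if (is.matrix(batch)) {
    if (nrow(batch) != side^2) stop(sprintf("patches must have %d pixels", side^2))
    return(batch)
  }
  d <- dim(batch)
  if (is.null(d)) stop("batch must be a matrix or array of patches")
  if (length(d) == 4L) {            # (side, side, 1, N)
    if (d[3] != 1L) stop("patches must be single-channel")
    d <- d[c(1, 2, 4)]
    dim(batch) <- d
  }
  if (length(d) == 2L) { dim(batch) <- c(d, 1L); d <- dim(batch) }
  if (d[1] != side || d[2] != side)
    stop(sprintf("patches must be %d x %d, got %d x %d", side, side, d[1], d[2]))
  matrix(batch, nrow = side^2)
}

#' Forward pass: class probabilities for a batch of patches
#'
#' @param model A `gacnn`.
#' @param batch Patches as a (side, side, N) or (side, side, 1, N) array, or
#'   a matrix with one flattened patch per column.
#' @param chunk Internal batch size for memory control.
#' @return An N x 2 matrix of class probabilities (columns: background,
#'   liver); rows sum to one.
#' @export
forward <- function(model, batch, chunk = 128L) {
  stopifnot(inherits(model, "gacnn"))
  side <- model$spec$input_shape[["side"]]
  X <- as_patch_matrix(batch, side)
  training <- identical(model$mode, "train")
  geom <- geom_matrix(model$spec)
  n <- ncol(X)
  out <- matrix(NA_real_, n, 2)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- cpp_gacnn_forward(model$params, X[, s:e, drop = FALSE], geom,
                                    unclass(model$spec$lrn),
                                    if (training) model$spec$dropout_rate else 0,
                                    training)
  }
  colnames(out) <- c("background", "liver")
  out
}
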