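#' Training configuration
#'
#' Defaults are the published recipe: stochastic gradient descent with
#' momentum 0.9, L2 weight decay 1e-4, 70 epochs of mini-batches of 64, and
#' a piecewise learning-rate schedule starting at 0.01 and dropping by a
#' factor of 0.1 every 20 epochs. Weights are initialized from a zero-mean
#' Gaussian with standard deviation `sigma_init`.
#'
#' @param max_epochs Number of epochs (>= 0).
#' @param batch_size Mini-batch size (>= 1).
#' @param momentum Momentum coefficient in [0, 1).
#' @param weight_decay L2 penalty coefficient (applied to weights, not
#'   biases).
#' @param lr_initial Initial learning rate (> 0).
#' @param lr_drop_factor Multiplicative drop applied every
#'   `lr_drop_period` epochs.
#' @param lr_drop_period Epochs between drops.
#' @param sigma_init Gaussian initialization standard deviation.
#' @param validation_fraction Fraction of patches held out for validation,
#'   in (0, 1); the split is stratified by class.
#' @param seed Integer seed governing shuffling, dropout and the split.
#' @param checkpoint_every Save a checkpoint every this many epochs
#'   (0 = never).
#' @param checkpoint_dir Directory for checkpoints.
#' @param verbose Emit one parseable log line per epoch.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 70L, batch_size = 64L, momentum = 0.9,
                         weight_decay = 1e-4, lr_initial = 0.01,
                         lr_drop_factor = 0.1, lr_drop_period = 20L,
                         sigma_init = 1e-4, validation_fraction = 0.1,
                         seed = 1L, checkpoint_every = 0L,
                         checkpoint_dir = NULL, verbose = FALSE) {
  if (lr_initial <= 0) stop("lr_initial must be > 0")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must lie in (0, 1)")
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, lr_initial = lr_initial,
                 lr_drop_factor = lr_drop_factor,
                 lr_drop_period = as.integer(lr_drop_period),
                 sigma_init = sigma_init,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_dir = checkpoint_dir, verbose = verbose),
            class = "train_config")
}

#' Logistic training cost with weight decay
#'
#' Mean negative log-likelihood of the liver-class probability,
#' `-(1/m) * sum(y * log p1 + (1 - y) * log(1 - p1))`, with probabilities
#' clipped away from \{0, 1\} by 1e-12 before the logs, plus
#' `(weight_decay / 2) * sum(w^2)` over the supplied weights.
#'
#' @param probabilities N x 2 matrix of class probabilities (column 2 =
#'   liver) or a vector of liver-class probabilities.
#' @param labels N labels in \{0, 1\}.
#' @param model_weights List of weight arrays entering the decay term
#'   (biases excluded by convention); `NULL` for none.
#' @param weight_decay L2 coefficient.
#' @return Scalar cost.
#' @export
cost <- function(probabilities, labels, model_weights = NULL, weight_decay = 0) {
  p1 <- if (is.matrix(probabilities)) probabilities[, 2] else probabilities
  if (!all(labels %in% c(0, 1))) stop("labels must lie in {0, 1}")
  if (length(p1) != length(labels)) stop("probabilities and labels differ in length")
  eps <- 1e-12
  p1 <- pmin(pmax(p1, eps), 1 - eps)
  nll <- -mean(labels * log(p1) + (1 - labels) * log(1 - p1))
  decay <- if (is.null(model_weights)) 0 else
    (weight_decay / 2) * sum(vapply(model_weights, function(w) sum(w^2), 0))
  nll + decay
}

#' Learning rate at a given epoch under the piecewise schedule
#'
#' `lr_initial * lr_drop_factor ^ floor((epoch - 1) / lr_drop_period)`:
#' with the default recipe, 0.01 for epochs 1-20, 0.001 for 21-40, 1e-4 for
#' 41-60 and 1e-5 for 61-70.
#'
#' @param epoch 1-based epoch in `1..max_epochs`.
#' @param config A [train_config()].
#' @return Scalar learning rate.
#' @export
lr_at <- function(epoch, config = train_config()) {
  if (any(epoch < 1 | epoch > config$max_epochs))
    stop(sprintf("epoch must lie in 1..%d", config$max_epochs))
  config$lr_initial * config$lr_drop_factor^((epoch - 1) %/% config$lr_drop_period)
}

#' One SGDM update
#'
#' `v <- momentum * v - lr * (grad + weight_decay * param)` followed by
#' `param <- param + v`. Weight decay is not applied to biases (parameters
#' whose names start with `"b"`). Accepts single arrays or named lists of
#' parameters.
#'
#' @param params Parameter array or named list of arrays.
#' @param grads Gradients of matching shape.
#' @param velocity Velocity state of matching shape (zeros to start).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 coefficient.
#' @return `list(params =, velocity =)` after the update.
#' @export
sgdm_step <- function(params, grads, velocity, lr, momentum, weight_decay = 0) {
  if (is.list(params)) {
    nm <- names(params)
    for (k in nm) {
      if (!all(is.finite(grads[[k]])))
        stop(sprintf("non-finite gradient in parameter '%s'", k))
      wd <- if (startsWith(k, "b")) 0 else weight_decay
      velocity[[k]] <- momentum * velocity[[k]] - lr * (grads[[k]] + wd * params[[k]])
      params[[k]] <- params[[k]] + velocity[[k]]
    }
    return(list(params = params, velocity = velocity))
  }
  if (!all(is.finite(grads))) stop("non-finite gradient")
  velocity <- momentum * velocity - lr * (grads + weight_decay * params)
  list(params = params + velocity, velocity = velocity)
}

model_weight_list <- function(params) params[grepl("^W", names(params))]

#' Train the network on a labeled patch set
#'
#' Runs seeded epochs of shuffled mini-batches under SGDM with the
#' piecewise learning-rate schedule, tracking training cost and validation
#' cost/accuracy per epoch. Gradients come from the C++ backward pass; the
#' update is [sgdm_step()]. A class-stratified validation split is held out
#' once before training.
#'
#' @param model A `gacnn` (see [init_gaussian()]).
#' @param patchset A `patch_set` from [extract_balanced()].
#' @param config A [train_config()].
#' @return `list(model =, history =)`; `history` has one row per completed
#'   epoch (epoch, lr, train_cost, val_cost, val_accuracy, checkpoint).
#' @export
fit <- function(model, patchset, config = train_config()) {
  stopifnot(inherits(model, "gacnn"), inherits(patchset, "patch_set"))
  n <- ncol(patchset$x)
  if (n == 0L) stop("empty patch set")
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_cost = numeric(), val_cost = numeric(),
                        val_accuracy = numeric(), checkpoint = character())
  if (config$max_epochs == 0L) return(list(model = model, history = history))

  geom <- geom_matrix(model$spec)
  lrnp <- unclass(model$spec$lrn)
  dropout <- model$spec$dropout_rate

  # stratified validation split
  split <- with_seed(derive_seed(config$seed, 777L), {
    val <- c()
    for (cl in c(0L, 1L)) {
      idx <- which(patchset$labels == cl)
      nv <- max(1L, round(length(idx) * config$validation_fraction))
      val <- c(val, sample(idx, min(nv, length(idx))))
    }
    val
  })
  tr_idx <- setdiff(seq_len(n), split)
  Xtr <- patchset$x[, tr_idx, drop = FALSE]
  ytr <- as.integer(patchset$labels[tr_idx])
  Xval <- patchset$x[, split, drop = FALSE]
  yval <- as.integer(patchset$labels[split])

  params <- model$params
  velocity <- lapply(params, function(p) p * 0)
  wkeys <- grepl("^W", names(params))

  with_seed(derive_seed(config$seed, 778L), {
    for (epoch in seq_len(config$max_epochs)) {
      lr <- lr_at(epoch, config)
      ord <- sample.int(length(ytr))
      costs <- c()
      for (s in seq(1L, length(ord), by = config$batch_size)) {
        b <- ord[s:min(length(ord), s + config$batch_size - 1L)]
        out <- cpp_gacnn_loss_grads(params, Xtr[, b, drop = FALSE], ytr[b],
                                    geom, lrnp, dropout)
        step <- sgdm_step(params, out$grads, velocity, lr, config$momentum,
                          config$weight_decay)
        params <- step$params
        velocity <- step$velocity
        costs <- c(costs, out$loss +
                     (config$weight_decay / 2) *
                     sum(vapply(params[wkeys], function(w) sum(w^2), 0)))
      }
      vp <- cpp_eval_probs(params, Xval, geom, lrnp)
      val_cost <- cost(vp, yval, params[wkeys], config$weight_decay)
      val_acc <- mean((vp[, 2] >= 0.5) == (yval == 1))
      ckpt <- NA_character_
      if (config$checkpoint_every > 0L && epoch %% config$checkpoint_every == 0L) {
        dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
        ckpt <- file.path(config$checkpoint_dir, sprintf("epoch_%03d.rds", epoch))
        m <- model; m$params <- params; m$epoch <- epoch
        saveRDS(m, ckpt)
      }
      history[nrow(history) + 1L, ] <-
        list(epoch, lr, mean(costs), val_cost, val_acc, ckpt)
      if (isTRUE(config$verbose))
        message(sprintf("epoch %d lr %.3e train_cost %.6f val_cost %.6f val_acc %.4f",
                        epoch, lr, mean(costs), val_cost, val_acc))
    }
  })
  model$params <- params
  model$epoch <- config$max_epochs
  model <- set_mode(model, "eval")
  list(model = model, history = history)
}

# Eval-mode probabilities straight from a parameter list (used inside fit,
# where no gacnn object exists for the current parameters).
cpp_eval_probs <- function(params, X, geom, lrnp, chunk = 128L) {
  n <- ncol(X)
  out <- matrix(NA_real_, n, 2)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    out[s:e, ] <- cpp_gacnn_forward(params, X[, s:e, drop = FALSE], geom, lrnp,
                                    0, FALSE)
  }
  out
}
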