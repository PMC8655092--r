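#' Training configuration
#'
#' @param epochs number of passes over the data.
#' @param batch_size mini-batch size.
#' @param momentum inertia `gamma` of the velocity update.
#' @param weight_decay regularization `lambda`.
#' @param lr_scale multiplier applied to [lr_schedule()]; lets the stepwise
#'   schedule drive a backbone whose stable step size differs from the
#'   schedule's absolute level.
#' @param seed RNG seed; the whole run is reproducible from it.
#' @param channels conv widths of the bundled backbone.
#' @param pool_after indices of the conv blocks followed by 2x2 max
#'   pooling; fewer poolings keep the final feature maps -- and hence the
#'   heat maps -- at finer spatial resolution.
#' @param freeze_backbone train only the dense head, leaving conv and batch
#'   norm parameters at their initial values.
#' @param augment_flip add a horizontally flipped copy of each training
#'   image.
#' @param shuffle reshuffle the batch order each epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(epochs = 10L, batch_size = 32L, momentum = 0.9,
                         weight_decay = 1e-4, lr_scale = 1, seed = 1L,
                         channels = c(8L, 16L, 16L), pool_after = 1L,
                         freeze_backbone = FALSE,
                         augment_flip = FALSE, shuffle = TRUE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr_scale > 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 momentum = momentum, weight_decay = weight_decay,
                 lr_scale = lr_scale, seed = as.integer(seed),
                 channels = as.integer(channels),
                 pool_after = as.integer(pool_after),
                 freeze_backbone = isTRUE(freeze_backbone),
                 augment_flip = isTRUE(augment_flip),
                 shuffle = isTRUE(shuffle)),
            class = "train_config")
}

# Stack a list of raster images into a normalized (H, W, C, N) batch.
raster_stack <- function(images) {
  if (is.array(images) && length(dim(images)) == 4L) return(images / 255 - 0.5)
  d <- dim(images[[1]])
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , , i] <- unclass(images[[i]])
  x / 255 - 0.5
}

#' Train the classifier
#'
#' Trains the bundled small convolutional backbone (3x3 conv -> ReLU ->
#' batch norm blocks with max pooling, ending in [region_pool()] and a
#' dense softmax head) with cross-entropy loss, using [momentum_update()]
#' for every parameter and the stepwise [lr_schedule()]. The returned model
#' carries the per-class, per-map, per-region dense weights that the
#' heat-map layer reuses -- localization needs no box annotations beyond
#' these classification weights.
#'
#' @param dataset list with `images` (list of RGB `raster_image`s of one
#'   common size, or an (H, W, C, N) array of raw 0-255 pixels) and `labels`
#'   (integer/factor class per image; at least two classes).
#' @param config a [train_config()].
#' @return a `wssh_model`: backbone parameters, `class_weights`
#'   (classes x maps x 5 regions), class levels and the loss history.
#' @export
train_classifier <- function(dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  labels <- factor(dataset$labels)
  if (nlevels(labels) < 2L)
    stop("dataset must contain at least two classes", call. = FALSE)
  x <- raster_stack(dataset$images)
  y <- as.integer(labels)
  if (dim(x)[4] != length(y)) stop("images/labels length mismatch", call. = FALSE)
  if (config$augment_flip) {
    x <- array(c(x, x[, dim(x)[2]:1, , , drop = FALSE]), dim(x) * c(1, 1, 1, 2))
    y <- c(y, y)
  }
  n <- length(y)
  K <- nlevels(labels)
  set.seed(config$seed)
  params <- init_backbone(K, dim(x)[3], config$channels, config$pool_after)

  # one train_state per parameter tensor, addressed by path
  states <- new.env(parent = emptyenv())
  get_state <- function(key, w, lr) {
    s <- states[[key]]
    if (is.null(s))
      s <- train_state(w, learning_rate = lr, momentum = config$momentum,
                       weight_decay = config$weight_decay,
                       batch_n = config$batch_size)
    s$learning_rate <- lr
    s$weights <- w
    s
  }
  step <- function(key, w, g, lr) {
    s <- momentum_update(get_state(key, w, lr), g)
    states[[key]] <- s
    s$weights
  }

  losses <- numeric(config$epochs)
  onehot <- diag(K)[, y, drop = FALSE]         # (K, N)
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch, max(60L, config$epochs)) * config$lr_scale
    ord <- if (config$shuffle) sample.int(n) else seq_len(n)
    ep_loss <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[, , , idx, drop = FALSE]
      fwd <- backbone_forward(params, xb, training = TRUE)
      params <- fwd$params                     # running BN stats advance
      p <- apply(fwd$scores, 2, softmax_prob)  # (K, nb)
      yb <- onehot[, idx, drop = FALSE]
      ep_loss <- ep_loss - sum(log(pmax(p[yb == 1], 1e-12)))
      dscores <- (p - yb) / length(idx)
      grads <- backbone_backward(params, fwd, dscores)
      params$head$W <- step("head.W", params$head$W, grads$head$W, lr)
      params$head$b <- step("head.b", params$head$b, grads$head$b, lr)
      if (!config$freeze_backbone) {
        for (l in seq_along(params$conv)) {
          params$conv[[l]]$W <- step(paste0("conv", l, ".W"),
                                     params$conv[[l]]$W, grads$conv[[l]]$W, lr)
          params$conv[[l]]$b <- step(paste0("conv", l, ".b"),
                                     params$conv[[l]]$b, grads$conv[[l]]$b, lr)
          params$bn[[l]]$gamma <- step(paste0("bn", l, ".g"),
                                       params$bn[[l]]$gamma, grads$bn[[l]]$gamma, lr)
          params$bn[[l]]$beta <- step(paste0("bn", l, ".b"),
                                      params$bn[[l]]$beta, grads$bn[[l]]$beta, lr)
        }
      }
    }
    losses[epoch] <- ep_loss / n
  }
  params <- calibrate_bn(params, x, config$batch_size)
  structure(list(params = params, classes = levels(labels),
                 class_weights = head_class_weights(params),
                 config = config, loss_history = losses),
            class = "wssh_model")
}

# Dense-head weights reshaped to (classes, maps, 5 regions). Column k of
# head$W stacks (map, region) in region_pool_batch order: region varies
# after maps.
head_class_weights <- function(params) {
  n_maps <- params$channels[length(params$channels)]
  K <- params$n_classes
  cw <- array(0, c(K, n_maps, 5L),
              dimnames = list(NULL, NULL, paste0("r", 1:5)))
  for (k in seq_len(K)) cw[k, , ] <- matrix(params$head$W[, k], n_maps, 5L)
  cw
}

#' @export
print.wssh_model <- function(x, ...) {
  cat(sprintf("<wssh_model: %d classes (%s), %d feature maps, %d epochs>\n",
              length(x$classes), paste(x$classes, collapse = "/"),
              dim(x$class_weights)[2], length(x$loss_history)))
  invisible(x)
}

#' Forward pass of a trained model on one image
#'
#' Runs the backbone in inference mode (running batch-norm statistics) and
#' returns the final feature maps, pooled units, class scores and softmax
#' probabilities.
#'
#' @param model a `wssh_model`.
#' @param image an RGB `raster_image` of the training size.
#' @return list with `features` (Hf x Wf x n array), `pooled`
#'   ([region_pool()] output), `scores`, `probs`, `class` (predicted label).
#' @export
predict_image <- function(model, image) {
  stopifnot(inherits(model, "wssh_model"), is_raster(image))
  x <- array(unclass(image), c(dim(image), 1L)) / 255 - 0.5
  fwd <- backbone_forward(model$params, x, training = FALSE)
  features <- fwd$features[, , , 1, drop = TRUE]
  scores <- fwd$scores[, 1]
  probs <- softmax_prob(scores)
  list(features = features, pooled = region_pool(features),
       scores = scores, probs = probs,
       class = model$classes[which.max(probs)])
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint stores backbone weights, class weights and the training
#' configuration needed by the localization stage.
#'
#' @param model a `wssh_model`.
#' @param path checkpoint file path.
#' @return `save_model`: `path` invisibly; `load_model`: the `wssh_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "wssh_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "wssh_model")) stop("not a wssh_model checkpoint: ", path)
  m
}
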