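#' Single convolution unit
#'
#' Dot product between a filter vector and a flattened input window plus a
#' bias, passed through an activation: `c = phi(u . x + b)`.
#'
#' @param window numeric vector, the flattened input slice.
#' @param filter numeric vector of the same length.
#' @param bias scalar bias.
#' @param activation activation function `phi`; default ReLU.
#' @return scalar activation value.
#' @export
conv_unit <- function(window, filter, bias = 0,
                      activation = function(z) pmax(z, 0)) {
  if (length(window) != length(filter))
    stop("window and filter lengths differ (", length(window), " vs ",
         length(filter), ")", call. = FALSE)
  activation(sum(window * filter) + bias)
}

#' Mini-batch statistics
#'
#' Population mean and variance of a mini-batch,
#' `mu = (1/n) sum(x)` and `sigma^2 = (1/n) sum((x - mu)^2)`.
#'
#' @param batch numeric vector of activations (n >= 1).
#' @return a `batch_stats` list with `mean`, `var`, `n`.
#' @export
batch_stats <- function(batch) {
  if (length(batch) < 1L) stop("batch must be non-empty", call. = FALSE)
  mu <- mean(batch)
  structure(list(mean = mu, var = mean((batch - mu)^2), n = length(batch)),
            class = "batch_stats")
}

#' @rdname batch_stats
#' @param x numeric vector to normalize.
#' @param eps variance floor for numerical stability.
#' @return `batch_normalize`: the standardized batch (mean ~ 0, variance ~ 1).
#' @export
batch_normalize <- function(x, eps = 1e-8) {
  s <- batch_stats(x)
  (x - s$mean) / sqrt(s$var + eps)
}

#' Local response normalization across channels
#'
#' `Q(x, y, i) = P(x, y, i) * (gamma + alpha * sum_j P(x, y, j)^2) ^ (-B)`
#' with the sum over a channel neighborhood of `size` channels centered at
#' `i` (clamped at the ends). Suppresses a unit when its channel neighbors
#' respond strongly.
#'
#' @param features H x W x n array of (non-negative, ReLU) activations.
#' @param gamma additive offset (> 0).
#' @param alpha energy scale.
#' @param B exponent.
#' @param size channel neighborhood size (`Inf` for all channels).
#' @return array of the same shape.
#' @export
local_response_norm <- function(features, gamma = 2, alpha = 1e-4, B = 0.75,
                                size = 5) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  n <- dim(features)[3]
  sq <- features^2
  half <- if (is.infinite(size)) n else floor(size / 2)
  out <- features
  for (i in seq_len(n)) {
    j <- max(1L, i - half):min(n, i + half)
    energy <- apply(sq[, , j, drop = FALSE], c(1, 2), sum)
    out[, , i] <- features[, , i] * (gamma + alpha * energy)^(-B)
  }
  out
}

#' Global average pooling
#'
#' Spatial mean of each feature map: the GAP unit `A_n1` feeding the
#' classifier head and the heat-map weights.
#'
#' @param features H x W x n array.
#' @return numeric vector of n per-map means.
#' @export
global_avg_pool <- function(features) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  apply(features, 3, mean)
}

#' Region pooling into five units per map
#'
#' Pools each feature map into a global unit `A_n1` (the mean over all
#' `N_1` units) and four quadrant units `A_n2 .. A_n5` (means over the
#' top-left, top-right, bottom-left and bottom-right blocks; the top/left
#' blocks take the ceiling rows/columns for odd sizes). The quadrants cover
#' the map exactly once.
#'
#' @param features H x W x n array with H, W >= 2.
#' @return a `pooled_units` list: `global_unit` (length n), `region_units`
#'   (n x 4 matrix), `region_size` (`N_1 = H * W`).
#' @export
region_pool <- function(features) {
  stopifnot(is.array(features), length(dim(features)) == 3L)
  d <- dim(features)
  if (d[1] < 2L || d[2] < 2L)
    stop("region_pool needs maps of at least 2 x 2", call. = FALSE)
  hr <- seq_len(ceiling(d[1] / 2)); wr <- seq_len(ceiling(d[2] / 2))
  hb <- setdiff(seq_len(d[1]), hr); wb <- setdiff(seq_len(d[2]), wr)
  q <- cbind(
    apply(features[hr, wr, , drop = FALSE], 3, mean),
    apply(features[hr, wb, , drop = FALSE], 3, mean),
    apply(features[hb, wr, , drop = FALSE], 3, mean),
    apply(features[hb, wb, , drop = FALSE], 3, mean))
  colnames(q) <- paste0("A", 2:5)
  structure(list(global_unit = apply(features, 3, mean),
                 region_units = q, region_size = d[1] * d[2]),
            class = "pooled_units")
}

#' Optimizer state for the momentum update
#'
#' @param weights numeric array of parameters.
#' @param velocity matching array (default zeros).
#' @param learning_rate step size `eta` (> 0).
#' @param momentum inertia `gamma` in `[0, 1)`.
#' @param weight_decay regularization strength `lambda` in `[0, 1)`.
#' @param epoch current epoch counter.
#' @param batch_n the `n` dividing the decay term.
#' @return a `train_state` list.
#' @export
train_state <- function(weights, velocity = NULL, learning_rate = 0.1,
                        momentum = 0.9, weight_decay = 1e-4, epoch = 1L,
                        batch_n = 1L) {
  if (is.null(velocity)) velocity <- weights * 0
  if (!identical(dim(weights), dim(velocity)) ||
      length(weights) != length(velocity))
    stop("velocity shape must equal weights shape", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (momentum < 0 || momentum >= 1) stop("momentum must be in [0, 1)", call. = FALSE)
  if (weight_decay < 0 || weight_decay >= 1)
    stop("weight_decay must be in [0, 1)", call. = FALSE)
  structure(list(weights = weights, velocity = velocity,
                 learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, epoch = as.integer(epoch),
                 batch_n = as.integer(batch_n)),
            class = "train_state")
}

#' Momentum update with weight decay
#'
#' Velocity update `v' = gamma * v + eta * dC/dw + decay`, then
#' `w' = w - v'`. In the default `"gradient"` mode the decay term is the
#' gradient of the penalty `(lambda / 2n) sum(w^2)`, i.e. `(lambda / n) w`
#' per coordinate. Mode `"as_printed"` instead adds the scalar penalty
#' value itself to every velocity component -- the update exactly as the
#' source formula types it, kept for fidelity even though it adds a scalar
#' to a vector.
#'
#' @param state a [train_state()].
#' @param gradient `dC/dw`, same shape as the weights.
#' @param decay_mode `"gradient"` (default) or `"as_printed"`.
#' @return the updated `train_state`.
#' @export
momentum_update <- function(state, gradient,
                            decay_mode = c("gradient", "as_printed")) {
  stopifnot(inherits(state, "train_state"))
  decay_mode <- match.arg(decay_mode)
  if (length(gradient) != length(state$weights) ||
      !identical(dim(gradient), dim(state$weights)))
    stop("gradient shape must equal weights shape", call. = FALSE)
  w <- state$weights
  decay <- if (decay_mode == "gradient") {
    (state$weight_decay / state$batch_n) * w
  } else {
    state$weight_decay / (2 * state$batch_n) * sum(w^2)
  }
  v <- state$momentum * state$velocity + state$learning_rate * gradient + decay
  state$velocity <- v
  state$weights <- w - v
  state
}

#' Stepwise learning-rate schedule
#'
#' Piecewise-constant schedule over a 60-epoch run: 0.1 through epoch 25,
#' 0.01 through 37, 0.001 through 45, and 0.0001 through 60 (each printed
#' milestone is the last epoch of its plateau; the drop takes effect the
#' following epoch). Non-increasing in the epoch by construction.
#'
#' @param epoch integer epoch in `1 .. total_epochs`.
#' @param total_epochs length of the run (default 60).
#' @return the learning rate for that epoch.
#' @export
lr_schedule <- function(epoch, total_epochs = 60L) {
  if (!is.numeric(epoch) || length(epoch) != 1L || epoch != floor(epoch) ||
      epoch < 1 || epoch > total_epochs)
    stop("epoch must be an integer in 1..", total_epochs, call. = FALSE)
  if (epoch <= 25) 0.1 else if (epoch <= 37) 0.01 else if (epoch <= 45) 0.001 else 1e-4
}

#' Softmax class probabilities
#'
#' `P_c = exp(S_c) / sum_c exp(S_c)`, computed with the max-shift trick so
#' large scores do not overflow.
#'
#' @param scores numeric vector of per-class scores.
#' @return probability vector summing to 1.
#' @export
softmax_prob <- function(scores) {
  stopifnot(all(is.finite(scores)))
  z <- exp(scores - max(scores))
  z / sum(z)
}
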