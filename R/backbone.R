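# Small convolutional backbone: 3 conv blocks (3x3 same-padding conv ->
# ReLU -> batch norm, max-pool 2x2 after the first two blocks), ending in
# region pooling and a dense softmax head. Written as vectorized matrix
# algebra over batched arrays (H, W, C, N); im2col turns each conv into a
# single GEMM. Any backbone exposing the same forward contract (final
# feature maps + region-pooled head) can be plugged into the training loop.

he_init <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}

#' Initialize the bundled small backbone
#'
#' @param n_classes number of output classes.
#' @param in_channels input channels (3 for RGB).
#' @param channels conv channel widths, one per block; the last entry is the
#'   number of final feature maps feeding the heat-map layer.
#' @return an untrained `wssh_model` parameter list.
#' @keywords internal
init_backbone <- function(n_classes, in_channels = 3L, channels = c(8L, 16L, 16L),
                          pool_after = 1L) {
  nb <- length(channels)
  conv <- vector("list", nb)
  bn <- vector("list", nb)
  cin <- in_channels
  for (l in seq_len(nb)) {
    conv[[l]] <- list(W = he_init(9L * cin, channels[l]),
                      b = rep(0, channels[l]))
    bn[[l]] <- list(gamma = rep(1, channels[l]), beta = rep(0, channels[l]),
                    rmean = rep(0, channels[l]), rvar = rep(1, channels[l]))
    cin <- channels[l]
  }
  n_maps <- channels[nb]
  list(conv = conv, bn = bn,
       head = list(W = he_init(5L * n_maps, n_classes) * 0.1,
                   b = rep(0, n_classes)),
       channels = channels, in_channels = in_channels,
       n_classes = n_classes, pool_after = as.integer(pool_after))
}

# im2col for a 3x3 same-padding convolution on a batch (H, W, C, N):
# returns (H*W*N) x (9*C), column (c-1)*9 + t for offset t in row-major
# (dy, dx) order. Zero padding.
im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  xp <- array(0, c(H + 2L, W + 2L, C, N))
  xp[2:(H + 1), 2:(W + 1), , ] <- x
  out <- matrix(0, H * W * N, 9L * C)
  t <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    t <- t + 1L
    sl <- xp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE]
    # (H, W, C, N) -> columns per channel with rows ordered (pixel, image)
    sl <- aperm(sl, c(1, 2, 4, 3))
    dim(sl) <- c(H * W * N, C)
    out[, (seq_len(C) - 1L) * 9L + t] <- sl
  }
  out
}

# Adjoint of im2col3: scatter-add column gradients back to the input batch.
col2im3 <- function(dcols, H, W, C, N) {
  dxp <- array(0, c(H + 2L, W + 2L, C, N))
  t <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    t <- t + 1L
    sl <- dcols[, (seq_len(C) - 1L) * 9L + t, drop = FALSE]
    dim(sl) <- c(H, W, N, C)
    dxp[dy + seq_len(H), dx + seq_len(W), , ] <-
      dxp[dy + seq_len(H), dx + seq_len(W), , , drop = FALSE] +
      aperm(sl, c(1, 2, 4, 3))
  }
  dxp[2:(H + 1), 2:(W + 1), , , drop = FALSE]
}

conv_forward <- function(x, layer) {
  d <- dim(x)
  cols <- im2col3(x)
  out <- sweep(cols %*% layer$W, 2, layer$b, "+")
  cout <- ncol(layer$W)
  dim(out) <- c(d[1], d[2], d[4], cout)
  list(out = aperm(out, c(1, 2, 4, 3)), cols = cols)
}

conv_backward <- function(dout, cache, layer, in_dim) {
  d <- dim(dout)
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  dW <- crossprod(cache$cols, dm)
  db <- colSums(dm)
  dcols <- dm %*% t(layer$W)
  dx <- col2im3(dcols, in_dim[1], in_dim[2], in_dim[3], in_dim[4])
  list(dx = dx, dW = dW, db = db)
}

pool_forward <- function(x) {
  d <- dim(x)
  ri <- seq(1, d[1] - 1, by = 2); ci <- seq(1, d[2] - 1, by = 2)
  a <- x[ri, ci, , , drop = FALSE];     b <- x[ri, ci + 1, , , drop = FALSE]
  cc <- x[ri + 1, ci, , , drop = FALSE]; dd <- x[ri + 1, ci + 1, , , drop = FALSE]
  m <- pmax(pmax(a, b), pmax(cc, dd))
  list(out = m, cands = list(a, b, cc, dd), in_dim = d)
}

pool_backward <- function(dout, cache) {
  d <- cache$in_dim
  ri <- seq(1, d[1] - 1, by = 2); ci <- seq(1, d[2] - 1, by = 2)
  m <- pmax(pmax(cache$cands[[1]], cache$cands[[2]]),
            pmax(cache$cands[[3]], cache$cands[[4]]))
  dx <- array(0, d)
  taken <- array(FALSE, dim(m))
  route <- function(cand) {
    sel <- (cand == m) & !taken
    taken <<- taken | sel
    dout * sel
  }
  dx[ri, ci, , ] <- route(cache$cands[[1]])
  dx[ri, ci + 1, , ] <- route(cache$cands[[2]])
  dx[ri + 1, ci, , ] <- route(cache$cands[[3]])
  dx[ri + 1, ci + 1, , ] <- route(cache$cands[[4]])
  dx
}

# Batch norm over (H, W, N) per channel; population (1/m) variance as in
# the mini-batch statistics above.
bn_forward <- function(x, layer, training, eps = 1e-5, rho = 0.9) {
  d <- dim(x)
  xm <- aperm(x, c(1, 2, 4, 3))
  dim(xm) <- c(d[1] * d[2] * d[4], d[3])
  if (training) {
    mu <- colMeans(xm)
    vv <- colMeans(xm^2) - mu^2
    layer$rmean <- rho * layer$rmean + (1 - rho) * mu
    layer$rvar <- rho * layer$rvar + (1 - rho) * vv
  } else {
    mu <- layer$rmean; vv <- layer$rvar
  }
  invstd <- 1 / sqrt(vv + eps)
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, invstd, "*")
  out <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  dim(out) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(out, c(1, 2, 4, 3)), xhat = xhat, invstd = invstd,
       layer = layer, d = d, mu = mu, vv = vv, m = d[1] * d[2] * d[4])
}

bn_backward <- function(dout, cache) {
  d <- cache$d
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(d[1] * d[2] * d[4], d[3])
  m <- nrow(dm)
  dgamma <- colSums(dm * cache$xhat)
  dbeta <- colSums(dm)
  dxhat <- sweep(dm, 2, cache$layer$gamma, "*")
  t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2, cache$invstd, "*")
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

# Region pooling on a batch: (Hf, Wf, C, N) -> (C, 5, N), unit order
# (global, TL, TR, BL, BR) matching region_pool().
region_pool_batch <- function(x) {
  d <- dim(x)
  hr <- seq_len(ceiling(d[1] / 2)); wr <- seq_len(ceiling(d[2] / 2))
  hb <- setdiff(seq_len(d[1]), hr); wb <- setdiff(seq_len(d[2]), wr)
  blocks <- list(list(seq_len(d[1]), seq_len(d[2])),
                 list(hr, wr), list(hr, wb), list(hb, wr), list(hb, wb))
  out <- array(0, c(d[3], 5L, d[4]))
  for (k in 1:5) {
    bl <- blocks[[k]]
    out[, k, ] <- apply(x[bl[[1]], bl[[2]], , , drop = FALSE], c(3, 4), mean)
  }
  out
}

region_pool_backward <- function(dpooled, fdim) {
  H <- fdim[1]; W <- fdim[2]
  hr <- seq_len(ceiling(H / 2)); wr <- seq_len(ceiling(W / 2))
  hb <- setdiff(seq_len(H), hr); wb <- setdiff(seq_len(W), wr)
  dx <- array(0, fdim)
  spread <- function(rows, cols, k) {
    g <- dpooled[, k, ] / (length(rows) * length(cols))   # (C, N)
    add <- aperm(array(g, c(dim(dpooled)[1], dim(dpooled)[3],
                            length(rows), length(cols))), c(3, 4, 1, 2))
    dx[rows, cols, , ] <<- dx[rows, cols, , , drop = FALSE] + add
  }
  spread(seq_len(H), seq_len(W), 1)
  spread(hr, wr, 2); spread(hr, wb, 3); spread(hb, wr, 4); spread(hb, wb, 5)
  dx
}

# Replace the exponential running batch-norm statistics with exact
# population statistics measured over the full (batched) training set, so
# single-image inference matches the statistics training saw.
calibrate_bn <- function(params, x, batch_size) {
  nb <- length(params$conv)
  n <- dim(x)[4]
  acc <- lapply(seq_len(nb), function(l)
    list(sum_mu = 0, sum_sq = 0, m = 0))
  for (start in seq(1, n, by = batch_size)) {
    xb <- x[, , , start:min(start + batch_size - 1L, n), drop = FALSE]
    fwd <- backbone_forward(params, xb, training = TRUE)
    for (l in seq_len(nb)) {
      bn <- fwd$caches[[l]]$bn
      acc[[l]]$sum_mu <- acc[[l]]$sum_mu + bn$m * bn$mu
      acc[[l]]$sum_sq <- acc[[l]]$sum_sq + bn$m * (bn$vv + bn$mu^2)
      acc[[l]]$m <- acc[[l]]$m + bn$m
    }
  }
  for (l in seq_len(nb)) {
    mu <- acc[[l]]$sum_mu / acc[[l]]$m
    params$bn[[l]]$rmean <- mu
    params$bn[[l]]$rvar <- acc[[l]]$sum_sq / acc[[l]]$m - mu^2
  }
  params
}

# Full forward pass over a batch; returns scores plus caches for backprop
# and the final feature maps.
backbone_forward <- function(params, x, training = FALSE, use_lrn = FALSE) {
  nb <- length(params$conv)
  caches <- vector("list", nb)
  h <- x
  for (l in seq_len(nb)) {
    in_dim <- dim(h)
    cf <- conv_forward(h, params$conv[[l]])
    pre <- cf$out
    act <- pmax(pre, 0)
    bf <- bn_forward(act, params$bn[[l]], training)
    params$bn[[l]] <- bf$layer
    h <- bf$out
    caches[[l]] <- list(conv = cf, in_dim = in_dim, relu_mask = pre > 0, bn = bf)
    if (l %in% params$pool_after) {
      pf <- pool_forward(h)
      caches[[l]]$pool <- pf
      h <- pf$out
    }
  }
  if (use_lrn && !training) {
    for (n in seq_len(dim(h)[4]))
      h[, , , n] <- local_response_norm(h[, , , n, drop = TRUE])
  }
  pooled <- region_pool_batch(h)               # (C, 5, N)
  pm <- matrix(pooled, dim(pooled)[1] * 5L, dim(pooled)[3])  # (5C, N)
  scores <- sweep(t(params$head$W) %*% pm, 1, params$head$b, "+")  # (K, N)
  list(scores = scores, features = h, pooled = pooled, pm = pm,
       caches = caches, params = params)
}

# Backward pass from dScores ((K, N), already divided by batch size).
backbone_backward <- function(params, fwd, dscores) {
  grads <- list(conv = vector("list", length(params$conv)),
                bn = vector("list", length(params$bn)))
  grads$head <- list(W = fwd$pm %*% t(dscores), b = rowSums(dscores))
  dpm <- params$head$W %*% dscores                    # (5C, N)
  dpooled <- array(dpm, dim(fwd$pooled))
  dh <- region_pool_backward(dpooled, dim(fwd$features))
  nb <- length(params$conv)
  for (l in nb:1) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$pool)) dh <- pool_backward(dh, cache$pool)
    bb <- bn_backward(dh, cache$bn)
    grads$bn[[l]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
    dact <- bb$dx * cache$relu_mask
    cb <- conv_backward(dact, cache$conv, params$conv[[l]], cache$in_dim)
    grads$conv[[l]] <- list(W = cb$dW, b = cb$db)
    dh <- cb$dx
  }
  grads
}
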