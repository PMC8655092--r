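# Literal, loop-level reference implementations of the pixel operators.
# These stay deliberately naive (double loops, explicit sorts) so they are
# independent of the vectorized/compiled code paths they check.

clampi <- function(v, lo, hi) pmin(pmax(v, lo), hi)

# internal helpers used throughout the tests
chan <- fundusWSSH:::chan
mask_bits <- fundusWSSH:::mask_bits
heat_values <- fundusWSSH:::heat_values

oracle_median <- function(x, k) {
  H <- nrow(x); W <- ncol(x); h <- (k - 1) / 2
  out <- x
  for (i in 1:H) for (j in 1:W) {
    vals <- c()
    for (di in -h:h) for (dj in -h:h)
      vals <- c(vals, x[clampi(i + di, 1, H), clampi(j + dj, 1, W)])
    out[i, j] <- sort(vals)[(length(vals) + 1) / 2]
  }
  out
}

kirsch_masks <- function() {
  g <- matrix(c(5, 5, 5, -3, 0, -3, -3, -3, -3), 3, 3, byrow = TRUE)
  rot45 <- function(m) {
    # rotate the ring of 8 border cells by one step (45 degrees)
    ring <- c(m[1, 1], m[1, 2], m[1, 3], m[2, 3], m[3, 3], m[3, 2], m[3, 1], m[2, 1])
    ring <- ring[c(8, 1:7)]
    out <- m
    out[1, 1] <- ring[1]; out[1, 2] <- ring[2]; out[1, 3] <- ring[3]
    out[2, 3] <- ring[4]; out[3, 3] <- ring[5]; out[3, 2] <- ring[6]
    out[3, 1] <- ring[7]; out[2, 1] <- ring[8]
    out
  }
  masks <- list(g)
  for (d in 2:8) masks[[d]] <- rot45(masks[[d - 1]])
  masks
}

oracle_kirsch <- function(x) {
  H <- nrow(x); W <- ncol(x)
  masks <- kirsch_masks()
  out <- x * 0
  for (i in 1:H) for (j in 1:W) {
    best <- -Inf
    for (m in masks) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1)
        acc <- acc + m[di + 2, dj + 2] * x[clampi(i + di, 1, H), clampi(j + dj, 1, W)]
      best <- max(best, acc)
    }
    out[i, j] <- best
  }
  out
}

oracle_sobel <- function(x) {
  H <- nrow(x); W <- ncol(x)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  sy <- t(sx)
  gx <- x * 0; gy <- x * 0
  for (i in 1:H) for (j in 1:W) for (di in -1:1) for (dj in -1:1) {
    v <- x[clampi(i + di, 1, H), clampi(j + dj, 1, W)]
    gx[i, j] <- gx[i, j] + sx[di + 2, dj + 2] * v
    gy[i, j] <- gy[i, j] + sy[di + 2, dj + 2] * v
  }
  list(gx = gx, gy = gy, magnitude = sqrt(gx^2 + gy^2))
}

# Clipped-translate binary morphology (offsets outside the domain ignored).
oracle_erode <- function(a, dy, dx) {
  H <- nrow(a); W <- ncol(a)
  out <- a * 0
  for (i in 1:H) for (j in 1:W) {
    v <- 1
    for (t in seq_along(dy)) {
      ii <- i + dy[t]; jj <- j + dx[t]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && a[ii, jj] == 0) v <- 0
    }
    out[i, j] <- v
  }
  out
}

oracle_dilate <- function(a, dy, dx) {
  H <- nrow(a); W <- ncol(a)
  out <- a * 0
  for (i in 1:H) for (j in 1:W) {
    v <- 0
    for (t in seq_along(dy)) {
      ii <- i - dy[t]; jj <- j - dx[t]
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= W && a[ii, jj] == 1) v <- 1
    }
    out[i, j] <- v
  }
  out
}

oracle_gray_dilate <- function(f, dy, dx, bval) {
  H <- nrow(f); W <- ncol(f)
  out <- f * 0
  for (i in 1:H) for (j in 1:W) {
    best <- -Inf
    for (t in seq_along(dy))
      best <- max(best, f[clampi(i - dy[t], 1, H), clampi(j - dx[t], 1, W)] + bval[t])
    out[i, j] <- best
  }
  out
}

# Exhaustive between-class-variance threshold scan over 256 bins of
# [0, 255]; returns the intensity at the lower edge of the best bin.
oracle_otsu <- function(x) {
  b <- pmin(pmax(floor(x / 255 * 256), 0), 255)
  n <- length(x)
  best_t <- NA; best_v <- -Inf
  for (t in 1:255) {
    lo <- sum(b < t); hi <- n - lo
    if (lo == 0 || hi == 0) next
    m0 <- mean(b[b < t]); m1 <- mean(b[b >= t])
    v <- (lo / n) * (hi / n) * (m0 - m1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t * 255 / 256
}

# Histogram equalization of a channel by direct CDF mapping over 256 bins
# of [lo, hi]: out = lo + CDF(bin) * (hi - lo).
oracle_hist_equalize <- function(x, lo, hi) {
  nb <- 256L
  b <- pmin(pmax(floor((x - lo) / (hi - lo) * nb), 0), nb - 1)
  cdf <- cumsum(tabulate(as.vector(b) + 1L, nb)) / length(x)
  matrix(lo + cdf[b + 1L] * (nb - 1) / (nb - 1) * (hi - lo), nrow(x), ncol(x))
}

rand_gray <- function(H, W, rng = c(0, 255)) {
  raster_image(matrix(runif(H * W, rng[1], rng[2]), H, W), "GRAY")
}

rand_mask <- function(H, W, p = 0.5) {
  binary_mask(matrix(rbinom(H * W, 1, p), H, W))
}

lesion_union_mask <- function(truth) {
  binary_mask(pmax(fundusWSSH:::mask_bits(truth$exudate_mask),
                   fundusWSSH:::mask_bits(truth$hemorrhage_mask)))
}
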