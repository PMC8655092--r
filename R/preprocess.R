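#' Preprocessing configuration
#'
#' Bundles the tunable parameters of the fundus preprocessing chain:
#' median denoising, CLAHE on the LAB lightness channel, gamma correction,
#' and an optional Kirsch edge map of the result.
#'
#' @param median_kernel odd integer window side for the median filter (>= 3).
#' @param clahe_clip_limit positive clip limit, as a multiple of the uniform
#'   per-bin count of a tile histogram.
#' @param clahe_tile_grid integer `(rows, cols)` tile grid.
#' @param gamma_g positive luminance exponent `g`; the map is
#'   `I' = 255 * (I / 155) ^ (1 / g)`, clipped to the value range.
#' @param apply_kirsch if `TRUE` the chain ends with the Kirsch edge map of
#'   the grayscale conversion.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(median_kernel = 3L, clahe_clip_limit = 2,
                              clahe_tile_grid = c(8L, 8L), gamma_g = 1.2,
                              apply_kirsch = FALSE) {
  median_kernel <- as.integer(median_kernel)
  if (is.na(median_kernel) || median_kernel < 3L || median_kernel %% 2L == 0L)
    stop("median_kernel must be an odd integer >= 3", call. = FALSE)
  if (clahe_clip_limit <= 0) stop("clahe_clip_limit must be > 0", call. = FALSE)
  if (gamma_g <= 0) stop("gamma_g must be > 0", call. = FALSE)
  clahe_tile_grid <- as.integer(clahe_tile_grid)
  if (length(clahe_tile_grid) != 2L || any(clahe_tile_grid < 1L))
    stop("clahe_tile_grid must be two positive integers", call. = FALSE)
  structure(list(median_kernel = median_kernel,
                 clahe_clip_limit = clahe_clip_limit,
                 clahe_tile_grid = clahe_tile_grid,
                 gamma_g = gamma_g,
                 apply_kirsch = isTRUE(apply_kirsch)),
            class = "preprocess_config")
}

#' Median denoising
#'
#' Replaces each pixel by the median of its `kernel x kernel` neighborhood
#' (edge replication at the border), channel by channel. Removes impulsive
#' noise while preserving lesion and vessel edges.
#'
#' @param image a `raster_image`.
#' @param kernel odd integer window side, `3 <= kernel <= min(H, W)`.
#' @return a `raster_image` of the same shape, range and color space.
#' @export
median_denoise <- function(image, kernel = 3L) {
  stopifnot(is_raster(image))
  kernel <- as.integer(kernel)
  d <- dim(image)
  if (is.na(kernel) || kernel %% 2L == 0L || kernel < 3L || kernel > min(d[1:2]))
    stop("kernel must be odd, >= 3 and <= min(H, W)", call. = FALSE)
  out <- array(0, d)
  for (c in seq_len(d[3])) out[, , c] <- cpp_median_filter(chan(image, c), kernel)
  raster_like(out, image)
}

# CLAHE on a single channel: per-tile clipped histograms (nbins levels over
# `rng`), excess redistributed uniformly, per-tile CDF mappings blended by
# bilinear interpolation in tile-center coordinates. With one tile and a
# clip limit above the tile pixel count this is exact histogram
# equalization: out = CDF(bin) * (nbins - 1) rescaled to `rng`.
clahe_channel <- function(x, clip_limit, tiles, rng, nbins = 256L) {
  H <- nrow(x); W <- ncol(x)
  R <- tiles[1]; C <- tiles[2]
  span <- rng[2] - rng[1]
  bin <- pmin(pmax(floor((x - rng[1]) / span * nbins), 0), nbins - 1L)
  trow <- pmin(floor((row(x) - 1) * R / H), R - 1)
  tcol <- pmin(floor((col(x) - 1) * C / W), C - 1)
  tid <- trow * C + tcol
  maps <- matrix(0, R * C, nbins)
  for (t in 0:(R * C - 1)) {
    sel <- tid == t
    n <- sum(sel)
    h <- tabulate(bin[sel] + 1L, nbins)
    clip <- max(1, clip_limit * n / nbins)
    for (it in 1:8) {  # redistribute clipped excess uniformly
      excess <- sum(pmax(h - clip, 0))
      if (excess <= 1e-9) break
      h <- pmin(h, clip) + excess / nbins
    }
    h <- pmin(h, clip)
    maps[t + 1, ] <- cumsum(h) / sum(h) * (nbins - 1L)
  }
  # bilinear blend of the four surrounding tile mappings
  ty <- (row(x) - 0.5) * R / H - 0.5
  tx <- (col(x) - 0.5) * C / W - 0.5
  r0 <- pmin(pmax(floor(ty), 0), R - 1); r1 <- pmin(r0 + 1, R - 1)
  c0 <- pmin(pmax(floor(tx), 0), C - 1); c1 <- pmin(c0 + 1, C - 1)
  wy <- pmin(pmax(ty - r0, 0), 1); wx <- pmin(pmax(tx - c0, 0), 1)
  b1 <- as.vector(bin) + 1L
  lut <- function(r, c) maps[cbind(as.vector(r * C + c) + 1L, b1)]
  v <- (1 - wy) * ((1 - wx) * lut(r0, c0) + wx * lut(r0, c1)) +
    wy * ((1 - wx) * lut(r1, c0) + wx * lut(r1, c1))
  matrix(rng[1] + v / (nbins - 1L) * span, H, W)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Converts an RGB image to CIE LAB, applies CLAHE to the lightness channel
#' only (the `a` and `b` chroma channels pass through untouched), and
#' converts back to RGB. The clip limit bounds per-tile histogram counts so
#' noise in homogeneous retinal background is not over-amplified.
#'
#' @inheritParams median_denoise
#' @param clip_limit positive clip limit (multiple of the uniform bin count).
#' @param tile_grid integer `(rows, cols)` tile grid.
#' @param keep_lab return the LAB image (before reconversion) instead of RGB;
#'   mainly for inspecting the equalized lightness channel.
#' @return a `raster_image` (RGB, or LAB when `keep_lab = TRUE`).
#' @export
clahe_enhance <- function(image, clip_limit = 2, tile_grid = c(8L, 8L),
                          keep_lab = FALSE) {
  assert_colorspace(image, "RGB", "clahe_enhance")
  if (clip_limit <= 0) stop("clip_limit must be > 0", call. = FALSE)
  lab <- rgb_to_lab(image)
  d <- dim(lab)
  out <- unclass(lab)
  attributes(out) <- list(dim = d)
  out[, , 1] <- clahe_channel(chan(lab, 1), clip_limit, as.integer(tile_grid),
                              rng = c(0, 100))
  lab2 <- raster_image(out, "LAB", img_range(image))
  if (keep_lab) lab2 else lab_to_rgb(lab2)
}

#' Gamma correction
#'
#' Pointwise luminance map `I' = 255 * (I / 155) ^ (1 / g)`, applied per
#' channel and clipped to the declared range. The fixed point at `I = 155`
#' maps to 255 for every `g`, so values above 155 saturate; the default
#' `g > 1` lightens the dark retinal periphery ahead of optic-disc edge
#' extraction.
#'
#' @inheritParams median_denoise
#' @param g positive exponent.
#' @return a `raster_image` of the same shape and color space.
#' @export
gamma_correct <- function(image, g = 1.2) {
  stopifnot(is_raster(image))
  if (!is.numeric(g) || length(g) != 1L || g <= 0)
    stop("g must be a positive scalar", call. = FALSE)
  if (min(image) < 0) stop("gamma correction needs non-negative pixels", call. = FALSE)
  raster_like(255 * (unclass(image) / 155) ^ (1 / g), image)
}

#' Normalized gray-level histogram
#'
#' Empirical density `p(i) = n_i / n` of gray levels `0 .. L-1`, where `n_i`
#' counts pixels at (floored) level `i` and `n = H * W`.
#'
#' @param image a grayscale `raster_image` with values in `[0, L)`.
#' @param levels number of gray levels `L`.
#' @return a `histogram_density` list with fields `levels` and `density`.
#' @export
normalized_histogram <- function(image, levels = 256L) {
  assert_colorspace(image, "GRAY", "normalized_histogram")
  levels <- as.integer(levels)
  x <- floor(as.vector(chan(image, 1)))
  if (any(x < 0) || any(x >= levels))
    stop("pixel values must lie in [0, levels)", call. = FALSE)
  structure(list(levels = levels, density = tabulate(x + 1L, levels) / length(x)),
            class = "histogram_density")
}

#' Kirsch compass edge map
#'
#' Non-linear edge detector: the response at each pixel is the maximum over
#' the eight directional 3 x 3 Kirsch kernels (the +5/-3 compass masks) of
#' the correlation with the replicated-border neighborhood. A flat image has
#' zero response everywhere since each kernel sums to zero.
#'
#' @param image a grayscale `raster_image`, at least 3 x 3.
#' @param rescale if `TRUE` (default) the raw responses are min-max rescaled
#'   to the declared value range; `FALSE` returns raw responses (their range
#'   attribute then covers the attainable response span).
#' @return a grayscale `raster_image`.
#' @export
kirsch_edge_map <- function(image, rescale = TRUE) {
  assert_colorspace(image, "GRAY", "kirsch_edge_map")
  if (any(dim(image)[1:2] < 3L))
    stop("the 3 x 3 compass kernels need at least a 3 x 3 image", call. = FALSE)
  r <- cpp_kirsch(chan(image, 1))
  if (!rescale)
    return(raster_image(r, "GRAY", range(c(r, 0))))
  rng <- img_range(image)
  lo <- min(r); hi <- max(r)
  if (hi > lo) r <- (r - lo) / (hi - lo) * (rng[2] - rng[1]) + rng[1]
  raster_image(r, "GRAY", rng)
}

#' Run the full preprocessing chain
#'
#' Applies, in order: median denoising, CLAHE on the LAB lightness channel,
#' gamma correction, and (when `config$apply_kirsch`) the Kirsch edge map of
#' the grayscale conversion.
#'
#' @param image an RGB `raster_image`.
#' @param config a [preprocess_config()].
#' @param keep_intermediates attach the per-stage outputs as the
#'   `"intermediates"` attribute (for a stage-by-stage panel).
#' @return the final `raster_image` (RGB, or GRAY when the Kirsch stage runs).
#' @export
run_preprocess <- function(image, config = preprocess_config(),
                           keep_intermediates = FALSE) {
  stopifnot(inherits(config, "preprocess_config"))
  assert_colorspace(image, "RGB", "run_preprocess")
  stages <- list()
  run_stage <- function(name, f) {
    r <- tryCatch(f(), error = function(e)
      stop("preprocess stage '", name, "': ", conditionMessage(e), call. = FALSE))
    if (keep_intermediates) stages[[name]] <<- r
    r
  }
  x <- run_stage("median", function() median_denoise(image, config$median_kernel))
  x <- run_stage("clahe", function()
    clahe_enhance(x, config$clahe_clip_limit, config$clahe_tile_grid))
  x <- run_stage("gamma", function() gamma_correct(x, config$gamma_g))
  if (config$apply_kirsch)
    x <- run_stage("kirsch", function() kirsch_edge_map(to_luminance(x)))
  if (keep_intermediates) attr(x, "intermediates") <- stages
  x
}
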