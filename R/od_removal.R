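#' Grayscale conversion
#'
#' Standard luminance-weighted conversion
#' `L = 0.299 R + 0.587 G + 0.114 B`. With `eq4_product = TRUE` the
#' horizontally-adjacent product `G(i, j) = L(i, j) * L(i, j + 1)` is formed
#' instead (last column replicated) and rescaled back to the value range --
#' a normalization variant that darkens anything next to a dark pixel.
#'
#' @param image an RGB `raster_image`.
#' @param eq4_product use the adjacent-pixel product variant.
#' @return a grayscale `raster_image`.
#' @export
to_luminance <- function(image, eq4_product = FALSE) {
  assert_colorspace(image, "RGB", "to_luminance")
  L <- 0.299 * chan(image, 1) + 0.587 * chan(image, 2) + 0.114 * chan(image, 3)
  if (eq4_product) {
    W <- ncol(L)
    Lshift <- L[, c(2:W, W), drop = FALSE]
    L <- L * Lshift / img_range(image)[2]
  }
  raster_like(array(L, c(dim(L), 1L)), image, color_space = "GRAY")
}

#' Image gradient field
#'
#' First-order gradient by the 3 x 3 Sobel pair (edge replication):
#' magnitude `sqrt(Gx^2 + Gy^2)` and angle `atan(Gy / Gx)` in
#' `(-pi/2, pi/2]`, with the degenerate `Gx = Gy = 0` pixel assigned
#' angle 0.
#'
#' @param gray a grayscale `raster_image`, at least 3 x 3.
#' @return a `gradient_field` list with matrices `magnitude`, `angle`,
#'   `gx`, `gy`.
#' @export
gradient_field <- function(gray) {
  assert_colorspace(gray, "GRAY", "gradient_field")
  if (any(dim(gray)[1:2] < 3L))
    stop("the 3 x 3 gradient masks need at least a 3 x 3 image", call. = FALSE)
  s <- cpp_sobel(chan(gray, 1))
  gx <- s$gx; gy <- s$gy
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan(gy / gx)
  ang[gx == 0 & gy == 0] <- 0
  ang[gx == 0 & gy > 0] <- pi / 2
  ang[gx == 0 & gy < 0] <- pi / 2   # atan(-Inf) folded onto the open interval's end
  structure(list(magnitude = mag, angle = ang, gx = gx, gy = gy),
            class = "gradient_field")
}

# Exhaustive between-class-variance (Otsu) threshold over `nbins` levels of
# the declared range; returns the intensity at the lower edge of the best
# bin (lowest level on ties).
otsu_threshold <- function(x, rng, nbins = 256L) {
  span <- rng[2] - rng[1]
  b <- pmin(pmax(floor((x - rng[1]) / span * nbins), 0), nbins - 1L)
  p <- tabulate(as.vector(b) + 1L, nbins) / length(x)
  levels <- 0:(nbins - 1L)
  w0 <- cumsum(p)
  m0 <- cumsum(p * levels)
  mt <- m0[nbins]
  t <- 1:(nbins - 1L)
  w0t <- w0[t]; w1t <- 1 - w0t
  valid <- w0t > 0 & w1t > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mt * w0t[valid] - m0[t][valid])^2 / (w0t[valid] * w1t[valid])
  best <- t[which.max(bcv)]
  rng[1] + best * span / nbins
}

#' Global thresholding
#'
#' Binarizes a grayscale image: bit 1 where `f(x, y) >= T`. With
#' `T = "auto"` the threshold is selected by exhaustive between-class
#' variance maximization over 256 levels of the declared range (Otsu's
#' criterion), separating the histogram's background and object peaks.
#'
#' @param gray a grayscale `raster_image`.
#' @param T numeric threshold within the value range, or `"auto"`.
#' @return a [binary_mask()] with `threshold_used` set.
#' @export
global_threshold <- function(gray, T = "auto") {
  assert_colorspace(gray, "GRAY", "global_threshold")
  x <- chan(gray, 1)
  rng <- img_range(gray)
  if (identical(T, "auto")) {
    T <- otsu_threshold(x, rng)
  } else {
    if (!is.numeric(T) || length(T) != 1L || T < rng[1] || T > rng[2])
      stop("T must be 'auto' or a value within the declared range", call. = FALSE)
  }
  binary_mask((x >= T) * 1L, T)
}

#' Detected optic-disc circle
#'
#' @param center_a column (x) coordinate, 0-based.
#' @param center_b row (y) coordinate, 0-based.
#' @param radius_r radius in pixels (> 0).
#' @param score accumulator support (fraction of circumference voted).
#' @return an `od_circle` object.
#' @export
od_circle <- function(center_a, center_b, radius_r, score = NA_real_) {
  if (radius_r <= 0) stop("radius_r must be > 0", call. = FALSE)
  structure(list(center_a = as.numeric(center_a), center_b = as.numeric(center_b),
                 radius_r = as.numeric(radius_r), score = as.numeric(score)),
            class = "od_circle")
}

#' @export
print.od_circle <- function(x, ...) {
  cat(sprintf("<od_circle center (a=%g, b=%g), r=%g, score=%.3f>\n",
              x$center_a, x$center_b, x$radius_r, x$score))
  invisible(x)
}

err_no_disc <- function(msg) {
  stop(errorCondition(msg, class = c("fundusWSSH_no_disc", "error", "condition")))
}

#' Optic-disc detection
#'
#' Detection chain: luminance conversion, Sobel gradient magnitude,
#' Gaussian smoothing of the edge map, automatic global thresholding,
#' opening/closing cleanup, then a circular Hough accumulator over the
#' candidate radii using the parametrization
#' `x = a + r cos(theta), y = b + r sin(theta)`. Candidates are ranked by
#' supported arc length (completeness times circumference), which stops a
#' small but complete circle -- an exudate rim -- from outranking the disc;
#' ties break to the smaller radius, then row-major center, so the result
#' is fully deterministic. The blur and cleanup defaults are deliberately
#' light: a thick rim band lets large eccentric circles ride one side of
#' the band and outscore the true rim.
#'
#' @param image an RGB or grayscale `raster_image` (ideally preprocessed).
#' @param radius_range numeric `(r_min, r_max)` in pixels; default
#'   `(0.03, 0.15) * min(H, W)` -- the bounded fraction of the field a disc
#'   occupies.
#' @param sigma standard deviation of the Gaussian blur applied to the edge
#'   map before thresholding.
#' @param open_B,close_B structuring elements for the mask cleanup.
#' @param score_floor minimum accumulator support (fraction of the
#'   circumference); below it a `fundusWSSH_no_disc` error signals an image
#'   without a detectable disc.
#' @return an [od_circle()].
#' @export
detect_od <- function(image, radius_range = NULL, sigma = 1,
                      open_B = struct_element("disk", 1L),
                      close_B = struct_element("disk", 2L),
                      score_floor = 0.25) {
  stopifnot(is_raster(image))
  gray <- if (img_colorspace(image) == "RGB") to_luminance(image) else image
  d <- dim(gray)
  if (is.null(radius_range)) radius_range <- c(0.03, 0.15) * min(d[1:2])
  r_min <- max(2L, as.integer(floor(radius_range[1])))
  r_max <- as.integer(ceiling(radius_range[2]))
  if (!(r_min < r_max) || r_max >= min(d[1:2]) / 2)
    stop("need 0 < r_min < r_max < min(H, W) / 2", call. = FALSE)
  gf <- gradient_field(gray)
  if (max(gf$magnitude) <= 0)
    err_no_disc("no optic disc found: image has no edges")
  # Gaussian blur of the edge map, then rescale into the image range so the
  # auto threshold operates on its declared scale
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-half:half, sd = sigma)
  mag <- cpp_sepconv(gf$magnitude, k / sum(k))
  rng <- img_range(gray)
  mag_img <- raster_image(mag / max(mag) * (rng[2] - rng[1]) + rng[1], "GRAY", rng)
  mask <- global_threshold(mag_img, "auto")
  mask <- morph_close(morph_open(mask, open_B), close_B)
  bits <- mask_bits(mask)
  frac <- mean(bits)
  if (frac == 0 || frac > 0.5)
    err_no_disc("no optic disc found: edge mask degenerate")
  best <- cpp_hough_circle(bits, r_min:r_max)
  if (best$score < score_floor)
    err_no_disc(sprintf(
      "no optic disc found: accumulator peak %.3f below floor %.3f",
      best$score, score_floor))
  od_circle(center_a = best$col, center_b = best$row,
            radius_r = best$r, score = best$score)
}

#' Optic-disc excision
#'
#' Sets every pixel within distance `r + margin` of the detected center to
#' the fill value and returns the excised image together with the disc mask.
#' Membership uses `(x - a)^2 + (y - b)^2 <= (r + margin)^2`, so a pixel
#' exactly on the circle is included. Exudates share the disc's color, so
#' cutting the disc removes the dominant source of false lesion candidates.
#'
#' @param image a `raster_image`.
#' @param circle an [od_circle()].
#' @param margin extra radius in pixels (default 2).
#' @param fill `"black"` (range minimum) or `"median"` (per-channel median
#'   of the pixels outside the disc).
#' @return list with elements `image` (excised `raster_image`) and `mask`
#'   (the disc [binary_mask()]).
#' @export
remove_od <- function(image, circle, margin = 2, fill = c("black", "median")) {
  stopifnot(is_raster(image), inherits(circle, "od_circle"))
  fill <- match.arg(fill)
  d <- dim(image)
  yy <- matrix(0:(d[1] - 1L), d[1], d[2])
  xx <- matrix(0:(d[2] - 1L), d[1], d[2], byrow = TRUE)
  inside <- (xx - circle$center_a)^2 + (yy - circle$center_b)^2 <=
    (circle$radius_r + margin)^2
  out <- unclass(image)
  attributes(out) <- list(dim = d)
  for (c in seq_len(d[3])) {
    v <- out[, , c]
    fv <- if (fill == "black") img_range(image)[1] else stats::median(v[!inside])
    v[inside] <- fv
    out[, , c] <- v
  }
  list(image = raster_like(out, image, clip = FALSE),
       mask = binary_mask(inside * 1L))
}
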