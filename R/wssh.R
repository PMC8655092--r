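resolve_class <- function(weights, class_id) {
  K <- dim(weights)[1]
  if (is.character(class_id)) stop("class must be given as an index", call. = FALSE)
  if (!is.numeric(class_id) || length(class_id) != 1L || class_id < 1 ||
      class_id > K || class_id != floor(class_id))
    stop("unknown class: ", class_id, " (model has ", K, " classes)", call. = FALSE)
  as.integer(class_id)
}

as_weights <- function(weights) {
  if (inherits(weights, "wssh_model")) weights <- weights$class_weights
  if (!is.array(weights) || length(dim(weights)) != 3L)
    stop("weights must be a (classes x maps x regions) array or a wssh_model",
         call. = FALSE)
  weights
}

heat_map <- function(values, class_id) {
  structure(values, class_id = class_id, class = "heat_map")
}

heat_values <- function(h) {
  x <- unclass(h)
  attributes(x) <- list(dim = dim(x))
  x
}

#' Class-sensitive heat map
#'
#' The class activation map `H_c(x, y) = sum_n w_n^c f_n(x, y)`, weighting
#' each final-layer feature map by the class's global-region (GAP) dense
#' weight. High values mark the spatial evidence the classifier used for
#' class `c`.
#'
#' @param features Hf x Wf x n array of final-layer activations
#'   (`predict_image()$features`).
#' @param weights a `wssh_model` or its (classes x maps x regions)
#'   `class_weights` array.
#' @param class_id 1-based class index.
#' @return a `heat_map` (matrix with a `class_id` attribute).
#' @export
class_heatmap <- function(features, weights, class_id) {
  w <- as_weights(weights)
  c <- resolve_class(w, class_id)
  stopifnot(is.array(features), length(dim(features)) == 3L)
  n <- dim(features)[3]
  if (dim(w)[2] != n)
    stop("weights cover ", dim(w)[2], " maps but features have ", n, call. = FALSE)
  d <- dim(features)
  fm <- matrix(features, d[1] * d[2], n)
  heat_map(matrix(fm %*% w[c, , 1], d[1], d[2]), c)
}

#' Region-weighted sensitive heat map (WSSH)
#'
#' Per-region saliency maps
#' `I_cj(x, y) = sum_k (w_k1^c / 4 + w_kj^c) f_k(x, y)` for the four
#' quadrant regions `j = 2..5` (the global weight enters at a quarter of
#' its value -- one share per sub-region), combined into a single saliency
#' map by the elementwise maximum so any region's evidence stays visible.
#'
#' @inheritParams class_heatmap
#' @param combine `"max"` for the combined map (default) or `"none"` to get
#'   the four per-region maps as a list.
#' @return a `heat_map` with attribute `regions` (the list of `I_c2..I_c5`),
#'   or that list when `combine = "none"`.
#' @export
wssh_heatmap <- function(features, weights, class_id, combine = c("max", "none")) {
  combine <- match.arg(combine)
  w <- as_weights(weights)
  c <- resolve_class(w, class_id)
  if (dim(w)[3] < 2L)
    stop("region weights (regions >= 2) are required for the WSSH map", call. = FALSE)
  d <- dim(features)
  fm <- matrix(features, d[1] * d[2], d[3])
  regions <- lapply(2:dim(w)[3], function(j)
    matrix(fm %*% (w[c, , 1] / 4 + w[c, , j]), d[1], d[2]))
  names(regions) <- paste0("I_c", 2:dim(w)[3])
  if (combine == "none") return(regions)
  out <- Reduce(pmax, regions)
  h <- heat_map(out, c)
  attr(h, "regions") <- regions
  h
}

#' WSSH class score
#'
#' `S_c = (1 / N_1) sum_x sum_y sum_n W_n^c A^n_{x,y}` -- the mean over all
#' spatial units of the globally-weighted activations. Algebraically this
#' equals the spatial mean of [class_heatmap()] (the bias plays no part),
#' which is the identity that lets classification weights double as
#' localization weights.
#'
#' @inheritParams class_heatmap
#' @return a `class_score` list with `s_c` and `variant = "wssh"`.
#' @export
wssh_score <- function(features, weights, class_id) {
  h <- class_heatmap(features, weights, class_id)
  structure(list(s_c = mean(heat_values(h)), variant = "wssh",
                 class_id = attr(h, "class_id")),
            class = "class_score")
}

#' Region-pooled class score
#'
#' `S_c = sum_j sum_n w_nj^c A_nj` over every region whose weights exist --
#' the dense-head pre-softmax score (bias excluded).
#'
#' @param pooled a [region_pool()] result.
#' @inheritParams class_heatmap
#' @return a `class_score` list with `s_c` and `variant = "region"`.
#' @export
region_score <- function(pooled, weights, class_id) {
  stopifnot(inherits(pooled, "pooled_units"))
  w <- as_weights(weights)
  c <- resolve_class(w, class_id)
  units <- cbind(pooled$global_unit, pooled$region_units)
  nr <- min(ncol(units), dim(w)[3])
  s <- sum(vapply(seq_len(nr), function(j) sum(w[c, , j] * units[, j]), 0))
  structure(list(s_c = s, variant = "region", class_id = c),
            class = "class_score")
}

#' Upsample a heat map to image resolution
#'
#' Bilinear interpolation (align-corners convention: output corner pixels
#' coincide with input corners) so the coarse feature-map heat can be
#' compared with full-resolution masks.
#'
#' @param heat a `heat_map` or plain matrix.
#' @param target integer `(H, W)`, each at least the source size.
#' @param smooth_sigma optional Gaussian smoothing (pixels) applied after
#'   interpolation. Zero (the default) leaves the pure bilinear map, which
#'   reproduces source values exactly at grid points; a small positive
#'   sigma pulls the argmax onto the local center of heat mass, stabilizing
#'   the peak against the coarse feature grid's half-cell quantization.
#' @return a `heat_map` of size `target`.
#' @export
upsample_heatmap <- function(heat, target, smooth_sigma = 0) {
  v <- if (inherits(heat, "heat_map")) heat_values(heat) else as.matrix(heat)
  if (target[1] < nrow(v) || target[2] < ncol(v))
    stop("target must be at least the source size", call. = FALSE)
  out <- cpp_bilinear_resize(v, as.integer(target[1]), as.integer(target[2]))
  if (smooth_sigma > 0) {
    half <- max(1L, as.integer(ceiling(3 * smooth_sigma)))
    k <- stats::dnorm(-half:half, sd = smooth_sigma)
    out <- cpp_sepconv(out, k / sum(k))
  }
  heat_map(out, attr(heat, "class_id"))
}

#' Refine a coarse heat peak by local photometric contrast
#'
#' Heat maps inherit the final feature grid's resolution, so their argmax
#' carries a quantization error of about one feature cell. Lesions are
#' locally extreme in intensity (exudates bright, hemorrhages dark), so
#' within a small disc around the proposed peak the pixel with the largest
#' absolute deviation from its median-filtered surround pins the location:
#' the class evidence proposes the neighborhood, the image decides the
#' pixel. Deterministic (row-major scan keeps the first maximum).
#'
#' @param image the RGB `raster_image` the heat refers to.
#' @param peak integer `(row, col)` 0-based proposal (a heat argmax).
#' @param radius search radius in pixels.
#' @param median_kernel window of the median surround estimate.
#' @return refined 0-based `(row, col)`.
#' @export
refine_peak <- function(image, peak, radius = 4L, median_kernel = 7L) {
  stopifnot(is_raster(image))
  lum <- chan(to_luminance(image), 1)
  contrast <- abs(lum - cpp_median_filter(lum, as.integer(median_kernel)))
  H <- nrow(lum); W <- ncol(lum)
  best <- peak
  # start from the proposal's own contrast so ties keep the proposal
  bestv <- if (peak[1] >= 0 && peak[2] >= 0 && peak[1] < H && peak[2] < W)
    contrast[peak[1] + 1L, peak[2] + 1L] else -Inf
  for (dr in -radius:radius) for (dc in -radius:radius) {
    if (dr * dr + dc * dc > radius * radius) next
    rr <- peak[1] + dr; cc <- peak[2] + dc
    if (rr < 0 || cc < 0 || rr >= H || cc >= W) next
    v <- contrast[rr + 1L, cc + 1L]
    if (v > bestv + 1e-12) { bestv <- v; best <- c(rr, cc) }
  }
  as.integer(best)
}

#' Localize lesions in one image with a trained model
#'
#' The full localization stage: forward pass, region-weighted heat map for
#' the chosen class, upsampling with peak smoothing, optic-disc detection
#' and suppression, and thresholding into ROIs.
#'
#' @param model a `wssh_model`.
#' @param image an RGB `raster_image` of the model's input size.
#' @param class_id 1-based class index, or `"auto"` for the softmax argmax.
#' @param thresh_frac threshold fraction for [heatmap_to_roi()].
#' @param od `"detect"` (run [detect_od()]; detection failure disables
#'   suppression), `"none"`, or a [binary_mask()] / [od_circle()] to use
#'   directly.
#' @param margin disc mask margin in pixels (see [remove_od()]).
#' @param smooth_sigma heat smoothing passed to [upsample_heatmap()].
#' @param snap_radius radius of the [refine_peak()] contrast refinement of
#'   the reported peak; 0 disables it.
#' @param clip_relu passed to [heatmap_to_roi()].
#' @return list with `class_id`, `class`, `probs`, `heat` (upsampled
#'   `heat_map`), `heat_suppressed` (disc region floored, for peak-based
#'   evaluation), `peak` (the refined 0-based location of the strongest
#'   lesion evidence), `rois`, `od_circle` (or `NULL`), `od_mask` (or
#'   `NULL`).
#' @export
localize_lesions <- function(model, image, class_id = "auto",
                             thresh_frac = 0.2, od = "detect", margin = 2,
                             smooth_sigma = 1.5, snap_radius = 4L,
                             clip_relu = FALSE) {
  pr <- predict_image(model, image)
  cls <- if (identical(class_id, "auto")) which.max(pr$probs)
         else resolve_class(model$class_weights, class_id)
  heat <- wssh_heatmap(pr$features, model, cls)
  heat <- upsample_heatmap(heat, dim(image)[1:2], smooth_sigma = smooth_sigma)
  circ <- NULL; od_mask <- NULL
  if (inherits(od, "od_circle")) {
    circ <- od
  } else if (inherits(od, "binary_mask")) {
    od_mask <- od
  } else if (identical(od, "detect")) {
    circ <- tryCatch(detect_od(image), fundusWSSH_no_disc = function(e) NULL)
  } else if (!identical(od, "none")) {
    stop("od must be 'detect', 'none', a binary_mask or an od_circle",
         call. = FALSE)
  }
  if (!is.null(circ) && is.null(od_mask))
    od_mask <- remove_od(image, circ, margin)$mask
  rois <- heatmap_to_roi(heat, thresh_frac, od_mask, clip_relu = clip_relu)
  heat_sup <- heat
  if (!is.null(od_mask)) {
    v <- heat_values(heat)
    v[mask_bits(od_mask) == 1L] <- min(v)
    heat_sup <- heat_map(v, attr(heat, "class_id"))
  }
  peak <- argmax_rowmajor(heat_values(heat_sup))
  if (snap_radius > 0) peak <- refine_peak(image, peak, snap_radius)
  list(class_id = cls, class = model$classes[cls], probs = pr$probs,
       heat = heat, heat_suppressed = heat_sup, peak = peak, rois = rois,
       od_circle = circ, od_mask = od_mask)
}

# Row-major argmax (smallest row, then column, among ties), 0-based.
argmax_rowmajor <- function(v) {
  m <- max(v)
  hits <- which(v == m, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  unname(c(hits[1, 1], hits[1, 2])) - 1L
}

#' Threshold a heat map into lesion regions of interest
#'
#' Binarizes the heat at `frac * max(heat)`, optionally zeroes everything
#' inside the optic-disc mask, then extracts 8-connected components. Each
#' component becomes a `lesion_roi` (half-open 0-based bbox, peak location
#' and peak heat). Candidates whose bounding box still touches the disc
#' mask are discarded -- the suppression that removes the disc as a false
#' exudate. ROIs are sorted by descending peak score, ties by row-major
#' peak position; an empty list signals "no lesion localized".
#'
#' @param heat a `heat_map` (upsampled to image size when `od_mask` is
#'   given).
#' @param frac threshold fraction of the heat maximum, in (0, 1).
#' @param od_mask optional optic-disc [binary_mask()] of the same shape.
#' @param clip_relu zero out negative heat before thresholding.
#' @return list of `lesion_roi` objects (possibly empty).
#' @export
heatmap_to_roi <- function(heat, frac = 0.2, od_mask = NULL, clip_relu = FALSE) {
  if (!(is.numeric(frac) && length(frac) == 1L && frac > 0 && frac < 1))
    stop("frac must lie strictly between 0 and 1", call. = FALSE)
  v <- if (inherits(heat, "heat_map")) heat_values(heat) else as.matrix(heat)
  if (clip_relu) v <- pmax(v, 0)
  mx <- max(v)
  if (mx <= 0) return(list())
  bin <- (v >= frac * mx) * 1L
  ob <- NULL
  if (!is.null(od_mask)) {
    ob <- mask_bits(od_mask)
    if (!all(dim(ob) == dim(v)))
      stop("od_mask shape must match the heat map", call. = FALSE)
    bin[ob == 1L] <- 0L
  }
  lab <- cpp_label8(bin)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  rois <- list()
  for (k in seq_len(nlab)) {
    idx <- which(lab == k, arr.ind = TRUE)
    r0 <- min(idx[, 1]) - 1L; r1 <- max(idx[, 1])
    c0 <- min(idx[, 2]) - 1L; c1 <- max(idx[, 2])
    if (!is.null(ob) && any(ob[(r0 + 1L):r1, (c0 + 1L):c1] == 1L)) next
    vk <- v
    vk[lab != k] <- -Inf
    peak <- argmax_rowmajor(vk)
    rois[[length(rois) + 1L]] <- structure(
      list(bbox = c(r0, c0, r1, c1), peak = peak,
           score = v[peak[1] + 1L, peak[2] + 1L]),
      class = "lesion_roi")
  }
  if (length(rois) == 0L) return(list())
  ord <- order(-vapply(rois, `[[`, 0, "score"),
               vapply(rois, function(r) r$peak[1], 0),
               vapply(rois, function(r) r$peak[2], 0))
  rois[ord]
}

#' Warp a region of interest to a fixed size
#'
#' Crops the ROI's bounding box from the image and resizes it to `out_size`
#' by bilinear interpolation -- the warping operator that standardizes
#' lesion patches for inspection or downstream scoring.
#'
#' @param image a `raster_image`.
#' @param roi a `lesion_roi` (from [heatmap_to_roi()]).
#' @param out_size integer `(h, w)` of the output patch.
#' @return a `raster_image` of size `out_size`.
#' @export
warp_roi <- function(image, roi, out_size) {
  stopifnot(is_raster(image), inherits(roi, "lesion_roi"))
  d <- dim(image)
  b <- roi$bbox
  if (b[1] < 0 || b[2] < 0 || b[3] > d[1] || b[4] > d[2] ||
      b[1] >= b[3] || b[2] >= b[4])
    stop("roi bounding box falls outside the image", call. = FALSE)
  rows <- (b[1] + 1L):b[3]; cols <- (b[2] + 1L):b[4]
  out <- array(0, c(out_size[1], out_size[2], d[3]))
  for (c in seq_len(d[3]))
    out[, , c] <- cpp_bilinear_resize(chan(image, c)[rows, cols, drop = FALSE],
                                      as.integer(out_size[1]),
                                      as.integer(out_size[2]))
  raster_like(out, image)
}

#' Pointing-game localization check
#'
#' Scores a hit when the heat map's argmax (row-major tie-break) falls
#' inside the ground-truth lesion mask -- the standard evaluation for
#' weakly supervised localization.
#'
#' @param heat a `heat_map`, same shape as the mask (upsample first).
#' @param lesion_mask ground-truth [binary_mask()]; must be non-empty.
#' @return `TRUE` for a hit, `FALSE` otherwise.
#' @export
pointing_game <- function(heat, lesion_mask) {
  v <- if (inherits(heat, "heat_map")) heat_values(heat) else as.matrix(heat)
  mb <- mask_bits(lesion_mask)
  if (!all(dim(mb) == dim(v)))
    stop("heat and mask shapes differ; upsample the heat first", call. = FALSE)
  if (sum(mb) == 0L)
    stop("lesion mask is empty: ground truth undefined", call. = FALSE)
  p <- argmax_rowmajor(v)
  mb[p[1] + 1L, p[2] + 1L] == 1L
}
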