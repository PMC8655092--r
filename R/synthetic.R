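#' Synthetic fundus generator configuration
#'
#' Controls the rendered scene: a dark circular retinal field, a bright
#' yellowish optic disc, dark branching vessels, sharp-edged bright
#' exudates drawn from the disc's own color range (reproducing the
#' disc/exudate confusion the pipeline targets), and dark-red hemorrhage
#' dots. Lesion counts are non-decreasing in the retinopathy grade; grade 0
#' renders no lesions at all.
#'
#' @param image_size side of the square image in pixels.
#' @param od_radius_frac disc radius range as a fraction of the image side.
#' @param od_offset_frac disc center offset from the field center, as a
#'   fraction of the field radius.
#' @param exudate_count,hemorrhage_count lesion counts per grade 0..4.
#' @param exudate_radius_frac,hemorrhage_radius_frac lesion radius range as
#'   a fraction of the image side.
#' @param vessel_count range of vessel branches.
#' @param noise_sd Gaussian pixel noise standard deviation (0-255 scale).
#' @param od_contrast_margin required mean intensity gap between disc and
#'   field background (0-255 scale).
#' @param class_probs sampling probabilities of grades 0..4 for
#'   [generate_dataset()].
#' @return a `generator_config` list.
#' @export
generator_config <- function(image_size = 256L,
                             od_radius_frac = c(0.08, 0.12),
                             od_offset_frac = c(0.25, 0.45),
                             exudate_count = c(0L, 2L, 4L, 7L, 10L),
                             hemorrhage_count = c(0L, 1L, 3L, 5L, 8L),
                             exudate_radius_frac = c(0.02, 0.035),
                             hemorrhage_radius_frac = c(0.015, 0.03),
                             vessel_count = c(2L, 4L),
                             noise_sd = 3,
                             od_contrast_margin = 50,
                             class_probs = c(0.3, 0.2, 0.2, 0.15, 0.15)) {
  stopifnot(image_size >= 32, length(exudate_count) == 5L,
            length(hemorrhage_count) == 5L, length(class_probs) == 5L)
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class_probs must sum to 1", call. = FALSE)
  if (any(diff(exudate_count) < 0) || any(diff(hemorrhage_count) < 0))
    stop("lesion counts must be non-decreasing in grade", call. = FALSE)
  structure(as.list(environment()), class = "generator_config")
}

# Paint an anti-aliased disc onto the channel stack; returns the updated
# stack and the exact lattice mask (d <= r).
paint_disc <- function(px, cy, cx, r, color, soft = 1) {
  d <- sqrt((row(px[, , 1]) - 1 - cy)^2 + (col(px[, , 1]) - 1 - cx)^2)
  alpha <- pmin(pmax((r - d) / soft + 0.5, 0), 1)
  for (c in 1:3) px[, , c] <- (1 - alpha) * px[, , c] + alpha * color[c]
  list(px = px, mask = (d <= r) * 1L)
}

#' Render one synthetic fundus image with ground truth
#'
#' Deterministic given `(seed, grade, config)`. One RNG stream per
#' structure (disc, vessels, lesions, noise) is derived from the seed, so
#' changing the lesion load does not move the disc. Exudates are kept
#' outside the disc plus a safety ring, so localization ground truth is
#' unambiguous.
#'
#' @param seed integer seed.
#' @param grade retinopathy grade 0 (healthy) to 4 (proliferative).
#' @param config a [generator_config()].
#' @return list with `image` (RGB `raster_image`) and `truth` (a
#'   `synthetic_truth` list: `od_circle`, `exudate_mask`,
#'   `hemorrhage_mask`, `vessel_mask`, `grade`, `seed`).
#' @export
generate_fundus <- function(seed, grade, config = generator_config()) {
  if (!(is.numeric(grade) && length(grade) == 1L && grade %in% 0:4))
    stop("grade must be an integer in 0..4", call. = FALSE)
  stopifnot(inherits(config, "generator_config"))
  S <- config$image_size
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 4L)

  cy <- (S - 1) / 2; cx <- (S - 1) / 2
  field_r <- 0.47 * S
  px <- array(0, c(S, S, 3))
  d <- sqrt((row(px[, , 1]) - 1 - cy)^2 + (col(px[, , 1]) - 1 - cx)^2)
  infield <- d <= field_r
  shade <- 1 - 0.35 * pmin(d / field_r, 1)^2
  base <- c(150, 70, 45)
  for (c in 1:3) px[, , c] <- ifelse(infield, base[c] * shade, 0)

  # optic disc
  set.seed(subseeds[1])
  od_r <- stats::runif(1, config$od_radius_frac[1], config$od_radius_frac[2]) * S
  ang <- stats::runif(1, 0, 2 * pi)
  off <- stats::runif(1, config$od_offset_frac[1], config$od_offset_frac[2]) * field_r
  off <- min(off, field_r - od_r - 3)
  od_cy <- cy + off * sin(ang); od_cx <- cx + off * cos(ang)
  od_color <- c(250, 235, 150)
  pd <- paint_disc(px, od_cy, od_cx, od_r, od_color, soft = 1.2)
  px <- pd$px; od_mask <- pd$mask

  # vessels: quadratic Bezier branches out of the disc
  set.seed(subseeds[2])
  nv <- sample(config$vessel_count[1]:config$vessel_count[2], 1L)
  vessel_mask <- matrix(0L, S, S)
  for (v in seq_len(nv)) {
    a0 <- stats::runif(1, 0, 2 * pi)
    p0 <- c(od_cy, od_cx)
    p2 <- c(cy + 0.92 * field_r * sin(a0), cx + 0.92 * field_r * cos(a0))
    mid <- (p0 + p2) / 2
    p1 <- mid + stats::rnorm(2, 0, 0.12 * S)
    tt <- seq(0, 1, length.out = 4L * S)
    by <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
    bx <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
    wd <- stats::runif(1, max(1, S / 170), max(1.6, S / 110))
    ii <- round(by) + 1L; jj <- round(bx) + 1L
    keep <- ii >= 1 & ii <= S & jj >= 1 & jj <= S
    half <- ceiling(wd)
    for (oy in -half:half) for (ox in -half:half) {
      if (oy^2 + ox^2 > wd^2) next
      i2 <- ii[keep] + oy; j2 <- jj[keep] + ox
      ok <- i2 >= 1 & i2 <= S & j2 >= 1 & j2 <= S
      vessel_mask[cbind(i2[ok], j2[ok])] <- 1L
    }
  }
  vessel_mask[!infield] <- 0L
  vcol <- c(90, 25, 20)
  for (c in 1:3) px[, , c] <- ifelse(vessel_mask == 1L,
                                     0.15 * px[, , c] + 0.85 * vcol[c], px[, , c])

  # lesions (exudates share the disc's color; hemorrhages are dark red)
  set.seed(subseeds[3])
  ex_mask <- matrix(0L, S, S); he_mask <- matrix(0L, S, S)
  placed <- matrix(numeric(0), 0, 3)   # (cy, cx, r) of earlier lesions
  place <- function(r_les) {
    for (try in 1:200) {
      aa <- stats::runif(1, 0, 2 * pi)
      dd <- sqrt(stats::runif(1)) * (field_r - r_les - 2)
      yy <- cy + dd * sin(aa); xx <- cx + dd * cos(aa)
      clear_od <- sqrt((yy - od_cy)^2 + (xx - od_cx)^2) > od_r + r_les + 3
      clear_les <- nrow(placed) == 0 ||
        all(sqrt((yy - placed[, 1])^2 + (xx - placed[, 2])^2) >
              placed[, 3] + r_les + 1)
      if (clear_od && clear_les) {
        placed <<- rbind(placed, c(yy, xx, r_les))
        return(c(yy, xx))
      }
    }
    NULL
  }
  for (k in seq_len(config$exudate_count[grade + 1L])) {
    r_les <- stats::runif(1, config$exudate_radius_frac[1],
                          config$exudate_radius_frac[2]) * S
    p <- place(r_les)
    if (is.null(p)) next
    col_les <- pmin(pmax(od_color + stats::rnorm(3, 0, 4), 0), 255)
    pd <- paint_disc(px, p[1], p[2], r_les, col_les, soft = 0.5)
    px <- pd$px; ex_mask <- pmax(ex_mask, pd$mask)
  }
  for (k in seq_len(config$hemorrhage_count[grade + 1L])) {
    r_les <- stats::runif(1, config$hemorrhage_radius_frac[1],
                          config$hemorrhage_radius_frac[2]) * S
    p <- place(r_les)
    if (is.null(p)) next
    pd <- paint_disc(px, p[1], p[2], r_les, c(70, 15, 15), soft = 0.5)
    px <- pd$px; he_mask <- pmax(he_mask, pd$mask)
  }

  set.seed(subseeds[4])
  noise <- array(stats::rnorm(S * S * 3, 0, config$noise_sd), c(S, S, 3))
  for (c in 1:3) px[, , c] <- px[, , c] + ifelse(infield, noise[, , c], 0)
  px <- pmin(pmax(px, 0), 255)

  truth <- structure(list(
    od_circle = od_circle(center_a = od_cx, center_b = od_cy, radius_r = od_r),
    exudate_mask = binary_mask(ex_mask),
    hemorrhage_mask = binary_mask(he_mask),
    vessel_mask = binary_mask(vessel_mask),
    grade = as.integer(grade), seed = as.integer(seed)),
    class = "synthetic_truth")
  list(image = raster_image(px, "RGB"), truth = truth)
}

#' Generate a labeled synthetic dataset
#'
#' Samples `n` grades from `config$class_probs` under a seeded RNG and
#' renders one fundus per draw. In-memory by default; with `dir` set it
#' also writes PNG images, a `labels.csv` (filename, grade) compatible with
#' [train_classifier()] input, per-image ground-truth JSON sidecars and
#' mask PNGs.
#'
#' @param n number of images (>= 1).
#' @param config a [generator_config()].
#' @param seed integer seed for grade sampling and per-image seeds.
#' @param dir optional output directory.
#' @param grades optional explicit grade vector (overrides `class_probs`).
#' @param render set to `FALSE` to draw only grades and per-image seeds
#'   (no rendering) -- for calibration checks of the grade sampler.
#' @return list with `images`, `truths`, `labels` (integer grades), and
#'   `files` (data frame, when `dir` is given).
#' @export
generate_dataset <- function(n, config = generator_config(), seed = 1L,
                             dir = NULL, grades = NULL, render = TRUE) {
  stopifnot(n >= 1)
  set.seed(seed)
  if (is.null(grades)) {
    grades <- sample(0:4, n, replace = TRUE, prob = config$class_probs)
  } else {
    stopifnot(length(grades) == n, all(grades %in% 0:4))
  }
  seeds <- sample.int(.Machine$integer.max - 1L, n)
  if (!render) return(list(labels = as.integer(grades), seeds = seeds))
  images <- vector("list", n); truths <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_fundus(seeds[i], grades[i], config)
    images[[i]] <- g$image; truths[[i]] <- g$truth
  }
  out <- list(images = images, truths = truths, labels = as.integer(grades))
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
    dir.create(file.path(dir, "truth"), showWarnings = FALSE)
    fn <- sprintf("fundus_%04d.png", seq_len(n))
    for (i in seq_len(n)) {
      write_image(images[[i]], file.path(dir, fn[i]))
      tr <- truths[[i]]
      mask_file <- file.path("truth", sprintf("fundus_%04d_exudate.png", i))
      write_image(raster_image(
        array(mask_bits(tr$exudate_mask) * 255, c(config$image_size,
                                                  config$image_size, 1L)),
        "GRAY"), file.path(dir, mask_file))
      jsonlite::write_json(list(
        od_circle = list(a = tr$od_circle$center_a, b = tr$od_circle$center_b,
                         r = tr$od_circle$radius_r),
        grade = tr$grade, seed = tr$seed, exudate_mask = mask_file),
        file.path(dir, "truth", sprintf("fundus_%04d.json", i)),
        auto_unbox = TRUE, digits = NA)
    }
    files <- data.frame(filename = fn, grade = as.integer(grades))
    utils::write.csv(files, file.path(dir, "labels.csv"), row.names = FALSE)
    out$files <- files
  }
  out
}
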