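#' Raster image container
#'
#' A `raster_image` is a numeric H x W (x C) array carrying a declared value
#' range and color space. It is the carrier passed between every stage of the
#' pipeline: preprocessing, optic-disc removal, the classifier and the
#' heat-map layer all consume and return this type.
#'
#' @param pixels numeric matrix (grayscale) or H x W x C array.
#' @param color_space one of `"RGB"`, `"LAB"`, `"GRAY"`.
#' @param value_range length-2 numeric, inclusive bounds for pixel values.
#' @return an object of class `raster_image`.
#' @examples
#' img <- raster_image(matrix(0:255, 16, 16), "GRAY")
#' dim(img)
#' @export
raster_image <- function(pixels, color_space = c("RGB", "LAB", "GRAY"),
                         value_range = c(0, 255)) {
  color_space <- match.arg(color_space)
  if (is.matrix(pixels)) pixels <- array(pixels, dim = c(dim(pixels), 1L))
  if (!is.array(pixels) || length(dim(pixels)) != 3L)
    stop("`pixels` must be a matrix or an H x W x C array", call. = FALSE)
  storage.mode(pixels) <- "double"
  d <- dim(pixels)
  if (d[1] < 1L || d[2] < 1L)
    stop("image must have positive dimensions", call. = FALSE)
  if (color_space == "GRAY" && d[3] != 1L)
    stop("GRAY images must have exactly one channel", call. = FALSE)
  if (color_space != "GRAY" && d[3] != 3L)
    stop(color_space, " images must have exactly three channels", call. = FALSE)
  if (color_space != "LAB") {  # LAB channels live on heterogeneous scales
    rng <- range(pixels)
    if (rng[1] < value_range[1] - 1e-9 || rng[2] > value_range[2] + 1e-9)
      stop("pixel values fall outside the declared value_range", call. = FALSE)
  }
  structure(pixels, value_range = as.numeric(value_range),
            color_space = color_space, class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_image %d x %d x %d, %s, range [%g, %g]>\n",
              d[1], d[2], d[3], attr(x, "color_space"),
              attr(x, "value_range")[1], attr(x, "value_range")[2]))
  invisible(x)
}

is_raster <- function(x) inherits(x, "raster_image")

assert_colorspace <- function(image, space, what) {
  if (!is_raster(image))
    stop(what, ": input must be a raster_image", call. = FALSE)
  if (attr(image, "color_space") != space)
    stop(what, ": input must be in ", space, " color space, got ",
         attr(image, "color_space"), call. = FALSE)
  invisible(image)
}

#' @rdname raster_image
#' @param x object to query.
#' @export
img_channels <- function(x) dim(x)[3]

#' @rdname raster_image
#' @export
img_range <- function(x) attr(x, "value_range")

#' @rdname raster_image
#' @export
img_colorspace <- function(x) attr(x, "color_space")

# Rebuild a raster keeping metadata; clips to the declared range.
raster_like <- function(pixels, template, color_space = NULL, clip = TRUE) {
  rng <- attr(template, "value_range")
  cs <- if (is.null(color_space)) attr(template, "color_space") else color_space
  if (clip && cs != "LAB") pixels <- pmin(pmax(pixels, rng[1]), rng[2])
  raster_image(pixels, cs, rng)
}

# Channel extraction as a plain matrix.
chan <- function(image, i) {
  x <- unclass(image)
  attributes(x) <- list(dim = dim(x))
  matrix(x[, , i], dim(x)[1], dim(x)[2])
}

#' Read an image file into a raster_image
#'
#' Decodes PNG and TIFF natively (JPEG through EBImage when available) to an
#' 8-bit-scale RGB or grayscale raster with value range 0-255. 16-bit TIFF
#' input is rescaled to 0-255 with a warning.
#'
#' @param path file path; format chosen by extension.
#' @return a `raster_image`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path)
    if (max(arr) > 1 + 1e-9) {  # some writers hand back raw 16-bit counts
      warning("16-bit TIFF rescaled to 0-255: ", path)
      arr <- arr / max(arr)
    }
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG support requires the EBImage package: ", path, call. = FALSE)
    arr <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(arr)) == 3L) arr <- aperm(arr, c(2, 1, 3)) else arr <- t(arr)
  } else {
    stop("unsupported image format '", ext, "': ", path, call. = FALSE)
  }
  if (length(dim(arr)) == 3L && dim(arr)[3] >= 3L) {
    raster_image(arr[, , 1:3, drop = FALSE] * 255, "RGB")
  } else {
    if (length(dim(arr)) == 3L) arr <- arr[, , 1]
    raster_image(as.matrix(arr) * 255, "GRAY")
  }
}

#' Write a raster_image to a PNG file
#'
#' Pixels are scaled by the declared range to 8 bits; `read_image()` of the
#' written file reproduces the quantized pixels exactly.
#'
#' @param image a `raster_image` (RGB or GRAY).
#' @param path output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is_raster(image))
  rng <- img_range(image)
  x <- (unclass(image) - rng[1]) / (rng[2] - rng[1])
  attributes(x) <- list(dim = dim(x))
  if (dim(x)[3] == 1L) x <- matrix(x[, , 1], dim(x)[1], dim(x)[2])
  png::writePNG(pmin(pmax(x, 0), 1), path)
  invisible(path)
}

# sRGB <-> CIE Lab via grDevices; pixels in [0,255], L in [0,100],
# a/b roughly [-128, 127].
rgb_to_lab <- function(image) {
  assert_colorspace(image, "RGB", "rgb_to_lab")
  d <- dim(image)
  m <- cbind(as.vector(chan(image, 1)), as.vector(chan(image, 2)),
             as.vector(chan(image, 3))) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  raster_image(array(lab, dim = d), "LAB", img_range(image))
}

lab_to_rgb <- function(image) {
  assert_colorspace(image, "LAB", "lab_to_rgb")
  d <- dim(image)
  m <- cbind(as.vector(chan(image, 1)), as.vector(chan(image, 2)),
             as.vector(chan(image, 3)))
  rgb <- grDevices::convertColor(m, from = "Lab", to = "sRGB")
  raster_image(pmin(pmax(array(rgb * 255, dim = d), 0), 255), "RGB",
               img_range(image))
}
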