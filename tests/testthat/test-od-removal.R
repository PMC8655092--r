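test_that("luminance conversion matches the weighted sum, with the product variant", {
  white <- raster_image(array(255, c(4, 4, 3)), "RGB")
  expect_true(all(abs(unclass(to_luminance(white)) - 255) < 1e-9))

  set.seed(8)
  img <- raster_image(array(runif(4 * 4 * 3, 0, 255), c(4, 4, 3)), "RGB")
  want <- 0.299 * chan(img, 1) + 0.587 * chan(img, 2) + 0.114 * chan(img, 3)
  expect_equal(chan(to_luminance(img), 1), want)

  # product variant: a zero pixel annihilates its position
  px <- array(runif(4 * 5 * 3, 50, 255), c(4, 5, 3))
  px[2, 3, ] <- 0
  gp <- chan(to_luminance(raster_image(px, "RGB"), eq4_product = TRUE), 1)
  expect_equal(gp[2, 3], 0)
  expect_equal(gp[2, 2], 0)   # left neighbor multiplies into the zero too

  expect_error(to_luminance(rand_gray(4, 4)), "RGB")
})

test_that("gradient field matches the Sobel-mask loop oracle", {
  # linear ramp in the column direction: constant interior magnitude, angle 0
  ramp <- raster_image(matrix(rep(0:7 * 30, each = 8), 8, 8), "GRAY")
  gf <- gradient_field(ramp)
  expect_true(all(abs(gf$angle[2:7, 2:7]) < 1e-12))
  expect_equal(stats::sd(gf$magnitude[2:7, 2:7]), 0)

  flat <- gradient_field(raster_image(matrix(42, 5, 5), "GRAY"))
  expect_true(all(flat$magnitude == 0))
  expect_true(all(flat$angle == 0))

  set.seed(10)
  for (rep in 1:20) {
    x <- matrix(runif(25, 0, 255), 5, 5)
    gf <- gradient_field(raster_image(x, "GRAY"))
    o <- oracle_sobel(x)
    expect_equal(gf$magnitude, o$magnitude)
    expect_equal(gf$gx, o$gx)
    expect_equal(gf$gy, o$gy)
    sel <- o$gx != 0
    expect_equal(gf$angle[sel], atan(o$gy[sel] / o$gx[sel]))
  }
})

test_that("global thresholding implements the >= rule and the auto scan", {
  img <- rand_gray(6, 6, c(100, 200))
  expect_true(all(mask_bits(global_threshold(img, 50)) == 1))
  expect_true(all(mask_bits(global_threshold(img, min(img))) == 1))

  x <- matrix(c(rep(50, 18), rep(200, 18)), 6, 6)
  m <- global_threshold(raster_image(x, "GRAY"), "auto")
  T <- attr(m, "threshold_used")
  expect_gt(T, 50); expect_lt(T, 200)
  expect_equal(unname(mask_bits(m)), unname((x == 200) * 1L))

  set.seed(2)
  for (rep in 1:10) {
    img <- rand_gray(16, 16)
    T <- attr(global_threshold(img, "auto"), "threshold_used")
    expect_equal(T, oracle_otsu(chan(img, 1)))
  }

  expect_error(global_threshold(img, 300), "range")
})

test_that("binary opening/closing match the definitional oracles and their laws", {
  B <- struct_element("disk", 3)
  lone <- matrix(0L, 9, 9); lone[5, 5] <- 1L
  expect_true(all(mask_bits(morph_open(binary_mask(lone), B)) == 0))

  holey <- matrix(1L, 9, 9); holey[5, 5] <- 0L
  expect_true(all(mask_bits(morph_close(binary_mask(holey),
                                        struct_element("disk", 1))) == 1))

  set.seed(6)
  B2 <- struct_element("square", 1)
  for (rep in 1:25) {
    m <- rand_mask(16, 16)
    er <- morph_erode(m, B2); di <- morph_dilate(m, B2)
    expect_equal(unname(mask_bits(er)), unname(oracle_erode(mask_bits(m), B2$dy, B2$dx)))
    expect_equal(unname(mask_bits(di)), unname(oracle_dilate(mask_bits(m), B2$dy, B2$dx)))
    op <- morph_open(m, B2); cl <- morph_close(m, B2)
    # idempotence
    expect_identical(mask_bits(morph_open(op, B2)), mask_bits(op))
    expect_identical(mask_bits(morph_close(cl, B2)), mask_bits(cl))
    # anti-extensivity / extensivity
    expect_true(all(mask_bits(op) <= mask_bits(m)))
    expect_true(all(mask_bits(cl) >= mask_bits(m)))
  }
})

test_that("grayscale dilation is the sup-plus filter of the definition", {
  Bflat <- struct_element("square", 1)
  cimg <- raster_image(matrix(40, 6, 6), "GRAY")
  expect_true(all(unclass(gray_dilate(cimg, Bflat)) == 40))

  Boff <- struct_element("square", 1, values = rep(7, 9))
  expect_true(all(unclass(gray_dilate(cimg, Boff)) == 47))

  set.seed(13)
  for (rep in 1:20) {
    img <- rand_gray(6, 6)
    got <- chan(gray_dilate(img, Bflat), 1)
    expect_equal(got, oracle_gray_dilate(chan(img, 1), Bflat$dy, Bflat$dx,
                                         Bflat$values))
    # flat element = local maximum filter
    expect_true(all(got >= chan(img, 1)))
  }
})

test_that("optic-disc detection recovers the synthetic disc and fails cleanly", {
  g <- generate_fundus(31, 1, generator_config(image_size = 256L))
  tr <- g$truth$od_circle
  circ <- detect_od(g$image)
  expect_lt(sqrt((circ$center_a - tr$center_a)^2 +
                 (circ$center_b - tr$center_b)^2), 5)
  expect_lt(abs(circ$radius_r - tr$radius_r) / tr$radius_r, 0.10)

  # determinism across runs
  circ2 <- detect_od(g$image)
  expect_identical(circ, circ2)

  flat <- raster_image(array(128, c(64, 64, 3)), "RGB")
  expect_error(detect_od(flat), class = "fundusWSSH_no_disc")
})

test_that("two identical discs resolve by the documented tie-break", {
  # two equal rings in an otherwise empty edge mask, voted directly
  bits <- matrix(0L, 64, 64)
  th <- seq(0, 2 * pi, length.out = 200)
  for (cc in list(c(20, 20), c(44, 44))) {
    ii <- round(cc[1] + 8 * sin(th)) + 1L; jj <- round(cc[2] + 8 * cos(th)) + 1L
    bits[cbind(ii, jj)] <- 1L
  }
  b1 <- fundusWSSH:::cpp_hough_circle(bits, 6:10)
  b2 <- fundusWSSH:::cpp_hough_circle(bits, 6:10)
  expect_identical(b1, b2)
  # row-major tie-break picks the first center
  expect_true(b1$row <= 20 + 1 && b1$col <= 20 + 1)
})

test_that("disc excision fills the circle, reports its mask, and is idempotent", {
  g <- generate_fundus(17, 0, generator_config(image_size = 96L))
  circ <- g$truth$od_circle
  res <- remove_od(g$image, circ, margin = 0)
  # mask area close to pi r^2 (within one pixel ring)
  area <- sum(mask_bits(res$mask))
  r <- circ$radius_r
  expect_lt(abs(area - pi * r^2), 2 * pi * (r + 1))
  # boundary pixel at distance exactly r is included
  expect_true(all(unclass(res$image)[mask_bits(res$mask) == 1] == 0))

  res2 <- remove_od(res$image, circ, margin = 0)
  expect_equal(unclass(res2$image), unclass(res$image))
  expect_identical(mask_bits(res2$mask), mask_bits(res$mask))

  # mask covers the generator's disc pixels with a small margin
  g2 <- generate_fundus(18, 2, generator_config(image_size = 96L))
  res3 <- remove_od(g2$image, g2$truth$od_circle, margin = 2)
  d <- dim(g2$image)
  yy <- matrix(0:(d[1] - 1), d[1], d[2]); xx <- t(yy)
  true_od <- (xx - g2$truth$od_circle$center_a)^2 +
    (yy - g2$truth$od_circle$center_b)^2 <= g2$truth$od_circle$radius_r^2
  cover <- sum(mask_bits(res3$mask)[true_od]) / sum(true_od)
  expect_gte(cover, 0.99)
})
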