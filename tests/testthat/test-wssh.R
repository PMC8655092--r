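make_weights <- function(K, n, vals = NULL) {
  if (is.null(vals)) vals <- rnorm(K * n * 5)
  array(vals, c(K, n, 5))
}

test_that("class heat map is the weighted sum of feature maps", {
  f <- array(0, c(3, 3, 1)); f[, , 1] <- matrix(1:9, 3, 3)
  w <- make_weights(1, 1, rep(0, 5)); w[1, 1, 1] <- 1
  h <- class_heatmap(f, w, 1)
  expect_equal(heat_values(h), matrix(1:9, 3, 3))

  # brute-force triple loop oracle
  set.seed(21)
  f2 <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  w2 <- make_weights(3, 2)
  want <- matrix(0, 2, 2)
  for (x in 1:2) for (y in 1:2) for (n in 1:2)
    want[x, y] <- want[x, y] + w2[2, n, 1] * f2[x, y, n]
  expect_equal(heat_values(class_heatmap(f2, w2, 2)), want)

  # linear in the weights
  wa <- make_weights(1, 2); wb <- make_weights(1, 2)
  expect_equal(heat_values(class_heatmap(f2, wa + wb, 1)),
               heat_values(class_heatmap(f2, wa, 1)) +
                 heat_values(class_heatmap(f2, wb, 1)))

  expect_error(class_heatmap(f2, w2, 9), "class")
})

test_that("region-weighted WSSH map combines (w1/4 + wj) coefficients by maximum", {
  set.seed(22)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))

  # single map: w_region1 = 4, w_region2 = 1 gives coefficient 2 exactly
  f1 <- array(rnorm(16), c(4, 4, 1))
  w <- make_weights(1, 1, rep(0, 5))
  w[1, 1, 1] <- 4; w[1, 1, 2] <- 1
  regs <- wssh_heatmap(f1, w, 1, combine = "none")
  expect_equal(regs$I_c2, 2 * f1[, , 1])
  # other regions see only w1/4 = 1
  expect_equal(regs$I_c3, f1[, , 1])

  # zero region weights reduce I_c2 to the w1/4 heat map
  w0 <- make_weights(2, 3); w0[, , 2:5] <- 0
  q <- wssh_heatmap(f, w0, 1, combine = "none")
  w4 <- w0; w4[1, , 1] <- w0[1, , 1] / 4
  expect_equal(q$I_c2, heat_values(class_heatmap(f, w4, 1)))

  # combined saliency dominates each per-region map
  wr <- make_weights(2, 3)
  comb <- wssh_heatmap(f, wr, 2)
  for (r in attr(comb, "regions"))
    expect_true(all(heat_values(comb) >= r - 1e-12))
})

test_that("the WSSH score satisfies the CAM identity against the loop oracle", {
  set.seed(23)
  # constant heat map of value h scores h
  fc <- array(1, c(3, 3, 2))
  wc <- make_weights(1, 2, rep(0, 10)); wc[1, , 1] <- c(2, 3)
  expect_equal(wssh_score(fc, wc, 1)$s_c, 5)

  for (rep in 1:25) {
    f <- array(rnorm(3 * 4 * 3), c(3, 4, 3))
    w <- make_weights(2, 3)
    s <- wssh_score(f, w, 1)$s_c
    # identity with the heat-map mean
    expect_equal(s, mean(heat_values(class_heatmap(f, w, 1))), tolerance = 1e-6)
    # literal triple sum
    acc <- 0
    for (x in 1:3) for (y in 1:4) for (n in 1:3)
      acc <- acc + w[1, n, 1] * f[x, y, n]
    expect_equal(s, acc / 12)
  }
})

test_that("region score is the linear form over pooled units", {
  f <- array(0, c(2, 2, 1))
  f[, , 1] <- matrix(c(2, 2, 2, 2), 2, 2)
  p <- region_pool(f)
  w <- make_weights(1, 1, rep(0, 5))
  w[1, 1, 1] <- 0.5; w[1, 1, 2] <- 1
  # A_11 = 2 (global), A_12 = 2 (first quadrant): 0.5*2 + 1*2 = 3
  expect_equal(region_score(p, w, 1)$s_c, 3)

  wz <- make_weights(1, 1, rep(0, 5))
  expect_equal(region_score(p, wz, 1)$s_c, 0)

  # linearity in the pooled units
  set.seed(24)
  f2 <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  w2 <- make_weights(1, 2)
  s1 <- region_score(region_pool(f2), w2, 1)$s_c
  s2 <- region_score(region_pool(2 * f2), w2, 1)$s_c
  expect_equal(s2, 2 * s1)
})

test_that("bilinear upsampling preserves constants, order and the corner mean", {
  cst <- heat_values(upsample_heatmap(matrix(3.5, 2, 2), c(7, 9)))
  expect_true(all(abs(cst - 3.5) < 1e-12))

  m <- matrix(c(0, 2, 4, 6), 2, 2)
  up <- heat_values(upsample_heatmap(m, c(3, 3)))
  expect_equal(up[2, 2], mean(m))          # center = mean of the corners
  expect_equal(up[1, 1], m[1, 1]); expect_equal(up[3, 3], m[2, 2])

  set.seed(25)
  src <- matrix(rnorm(36), 6, 6)
  up2 <- heat_values(upsample_heatmap(src, c(24, 24)))
  pk <- which(up2 == max(up2), arr.ind = TRUE)[1, ]
  spk <- which(src == max(src), arr.ind = TRUE)[1, ]
  # argmax maps into the pre-image cell of the source argmax
  expect_lt(max(abs((pk - 1) / 23 * 5 - (spk - 1))), 1)

  expect_error(upsample_heatmap(src, c(4, 24)), "at least")
})

test_that("heat-map thresholding yields flood-fill components with OD suppression", {
  # single Gaussian bump: one ROI matching the half-max region
  g <- outer(dnorm(seq(-3, 3, length.out = 21)),
             dnorm(seq(-3, 3, length.out = 21)))
  rois <- heatmap_to_roi(g, frac = 0.5)
  expect_length(rois, 1)
  sel <- which(g >= 0.5 * max(g), arr.ind = TRUE)
  expect_equal(rois[[1]]$bbox,
               c(min(sel[, 1]) - 1L, min(sel[, 2]) - 1L,
                 max(sel[, 1]), max(sel[, 2])))
  expect_equal(rois[[1]]$peak, c(10L, 10L))
  # peak inside bbox (half-open convention)
  b <- rois[[1]]$bbox
  expect_true(rois[[1]]$peak[1] >= b[1] && rois[[1]]$peak[1] < b[3])

  # full suppression empties the list
  od <- binary_mask(matrix(1L, 21, 21))
  expect_length(heatmap_to_roi(g, 0.5, od), 0)

  # empty OD mask changes nothing
  od0 <- binary_mask(matrix(0L, 21, 21))
  r2 <- heatmap_to_roi(g, 0.5, od0)
  expect_equal(r2, rois)

  # two equal bumps: deterministic row-major ordering
  two <- matrix(0, 11, 11); two[3, 3] <- 1; two[9, 9] <- 1
  rt <- heatmap_to_roi(two, 0.5)
  expect_length(rt, 2)
  expect_equal(rt[[1]]$peak, c(2L, 2L))
  expect_equal(rt[[2]]$peak, c(8L, 8L))
  expect_identical(rt, heatmap_to_roi(two, 0.5))

  expect_error(heatmap_to_roi(g, 0), "frac")
  expect_error(heatmap_to_roi(g, 1.2), "frac")
})

test_that("no returned ROI touches the supplied optic-disc mask", {
  set.seed(26)
  for (rep in 1:20) {
    heat <- matrix(runif(32 * 32), 32, 32)
    od <- matrix(0L, 32, 32)
    cy <- sample(8:24, 1); cx <- sample(8:24, 1)
    od[(row(od) - cy)^2 + (col(od) - cx)^2 <= 36] <- 1L
    rois <- heatmap_to_roi(heat, 0.3, binary_mask(od))
    for (r in rois) {
      bb <- r$bbox
      expect_true(all(od[(bb[1] + 1):bb[3], (bb[2] + 1):bb[4]] == 0L))
    }
  }
})

test_that("ROI warping crops and resizes with identity fixed points", {
  set.seed(27)
  img <- raster_image(array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3)), "RGB")
  full <- structure(list(bbox = c(0L, 0L, 10L, 10L), peak = c(0L, 0L),
                         score = 1), class = "lesion_roi")
  expect_equal(unclass(warp_roi(img, full, c(10, 10))), unclass(img))

  crop <- structure(list(bbox = c(2L, 3L, 6L, 7L), peak = c(3L, 4L),
                         score = 1), class = "lesion_roi")
  w <- warp_roi(img, crop, c(4, 4))
  expect_equal(unclass(w)[, , 2], chan(img, 2)[3:6, 4:7])

  # 4x4 crop to 2x2: align-corner bilinear picks the crop's corners
  w2 <- warp_roi(img, crop, c(2, 2))
  sub <- chan(img, 1)[3:6, 4:7]
  expect_equal(unclass(w2)[, , 1],
               matrix(c(sub[1, 1], sub[4, 1], sub[1, 4], sub[4, 4]), 2, 2))

  bad <- structure(list(bbox = c(5L, 5L, 12L, 12L), peak = c(6L, 6L),
                        score = 1), class = "lesion_roi")
  expect_error(warp_roi(img, bad, c(3, 3)), "outside")
})

test_that("peak refinement snaps onto the locally extreme pixel and stays in bounds", {
  # flat gray field with one bright dot two pixels from the proposed peak
  px <- array(100, c(16, 16, 3))
  px[9, 11, ] <- 250
  img <- raster_image(px, "RGB")
  expect_equal(refine_peak(img, c(8L, 8L), radius = 3), c(8L, 10L))
  # outside the radius the proposal stands
  expect_equal(refine_peak(img, c(2L, 2L), radius = 3), c(2L, 2L))
  # dark dots attract too (hemorrhage case)
  px2 <- array(100, c(16, 16, 3))
  px2[5, 5, ] <- 5
  expect_equal(refine_peak(raster_image(px2, "RGB"), c(6L, 6L), radius = 3),
               c(4L, 4L))
  # corner proposals never leave the image
  p <- refine_peak(img, c(0L, 0L), radius = 3)
  expect_true(all(p >= 0 & p <= 15))
})

test_that("the pointing game hits exactly when the argmax is inside the mask", {
  h <- matrix(0, 8, 8); h[5, 6] <- 2
  m <- matrix(0L, 8, 8); m[5, 6] <- 1L
  expect_true(pointing_game(h, binary_mask(m)))
  m2 <- matrix(0L, 8, 8); m2[1, 1] <- 1L
  expect_false(pointing_game(h, binary_mask(m2)))
  expect_true(pointing_game(h, binary_mask(matrix(1L, 8, 8))))

  # uniform heat: row-major tie-break decides deterministically
  u <- matrix(1, 4, 4)
  corner <- matrix(0L, 4, 4); corner[1, 1] <- 1L
  expect_true(pointing_game(u, binary_mask(corner)))
  other <- matrix(0L, 4, 4); other[4, 4] <- 1L
  expect_false(pointing_game(u, binary_mask(other)))

  expect_error(pointing_game(h, binary_mask(matrix(0L, 8, 8))), "empty")
  expect_error(pointing_game(h, binary_mask(matrix(1L, 4, 4))), "shape")
})
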