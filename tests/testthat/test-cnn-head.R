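test_that("convolution unit computes phi(u.x + b)", {
  expect_equal(conv_unit(c(3, 4), c(1, 2), 1, identity), 12)
  expect_equal(conv_unit(rep(0, 6), rep(0, 6), 0), 0)
  set.seed(1)
  for (rep in 1:10) {
    u <- rnorm(9); x <- rnorm(9); b <- rnorm(1)
    expect_gte(conv_unit(x, u, b), 0)                       # ReLU range
    expect_equal(conv_unit(x, u, b, identity), sum(u * x) + b)
  }
  expect_error(conv_unit(1:3, 1:4), "length")
})

test_that("batch statistics use the population 1/n variance and normalize to unit scale", {
  s <- batch_stats(c(1, 2, 3))
  expect_equal(s$mean, 2)
  expect_equal(s$var, 2 / 3)
  expect_equal(s$n, 3L)

  expect_equal(batch_stats(rep(4.2, 10))$var, 0)

  set.seed(2)
  z <- batch_normalize(rnorm(64, 5, 3))
  expect_lt(abs(mean(z)), 1e-6)
  expect_lt(abs(mean((z - mean(z))^2) - 1), 1e-4)

  expect_error(batch_stats(numeric(0)), "non-empty")
})

test_that("local response normalization matches the closed form", {
  f <- array(0, c(1, 1, 2)); f[1, 1, ] <- c(1, 2)
  q <- local_response_norm(f, gamma = 1, alpha = 1, B = 0.5, size = Inf)
  expect_equal(q[1, 1, 1], 1 / sqrt(6))
  expect_equal(q[1, 1, 2], 2 / sqrt(6))

  # alpha = 0 reduces to a pure gamma^-B scaling
  set.seed(3)
  g <- array(abs(rnorm(3 * 3 * 4)), c(3, 3, 4))
  expect_equal(local_response_norm(g, gamma = 2, alpha = 0, B = 0.75),
               g * 2^(-0.75))

  # raising a neighbor's energy never raises the normalized response
  g2 <- g; g2[2, 2, 2] <- g2[2, 2, 2] + 5
  q1 <- local_response_norm(g, size = Inf)
  q2 <- local_response_norm(g2, size = Inf)
  expect_lte(q2[2, 2, 1], q1[2, 2, 1])
})

test_that("global and region pooling expose the five-unit partition", {
  f <- array(0, c(2, 2, 1)); f[, , 1] <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(global_avg_pool(f), 2.5)
  p <- region_pool(f)
  expect_equal(p$global_unit, 2.5)
  expect_equal(unname(p$region_units[1, ]), c(1, 2, 3, 4))
  expect_equal(p$region_size, 4L)

  cst <- array(7, c(4, 6, 3))
  pc <- region_pool(cst)
  expect_true(all(abs(c(pc$global_unit, pc$region_units) - 7) < 1e-12))

  # pooling is linear; quadrant means average back to the global mean
  set.seed(4)
  a <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  b <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  expect_equal(global_avg_pool(2 * a + 3 * b),
               2 * global_avg_pool(a) + 3 * global_avg_pool(b))
  pa <- region_pool(a)
  expect_equal(rowMeans(pa$region_units), pa$global_unit)

  expect_error(region_pool(array(1, c(1, 4, 2))), "2 x 2")
})

test_that("momentum update follows the velocity form and degenerates to SGD", {
  st <- train_state(1, velocity = 0.5, learning_rate = 0.1, momentum = 0.9,
                    weight_decay = 0)
  st2 <- momentum_update(st, 2)
  expect_equal(st2$velocity, 0.9 * 0.5 + 0.1 * 2)   # 0.65
  expect_equal(st2$weights, 1 - 0.65)               # 0.35

  # gamma = 0, lambda = 0: plain gradient descent on every case
  set.seed(5)
  for (rep in 1:10) {
    w <- rnorm(4); g <- rnorm(4); eta <- runif(1, 0.01, 1)
    st <- train_state(w, learning_rate = eta, momentum = 0, weight_decay = 0)
    expect_equal(momentum_update(st, g)$weights, w - eta * g)
  }

  # zero gradient, zero velocity, no decay: fixed point
  st <- train_state(c(1, -2), learning_rate = 0.3, momentum = 0.9,
                    weight_decay = 0)
  expect_equal(momentum_update(st, c(0, 0))$weights, c(1, -2))

  # as-printed mode adds the scalar penalty itself
  stp <- train_state(c(1, 2), learning_rate = 0.1, momentum = 0,
                     weight_decay = 0.1, batch_n = 1)
  out <- momentum_update(stp, c(0, 0), decay_mode = "as_printed")
  expect_equal(out$velocity, rep(0.1 / 2 * 5, 2))

  expect_error(momentum_update(st, c(0, 0, 0)), "shape")
  expect_error(train_state(1, learning_rate = 0), "learning_rate")
})

test_that("the learning-rate schedule reproduces the printed plateaus", {
  expect_equal(lr_schedule(25), 0.1)
  expect_equal(lr_schedule(60), 1e-4)
  expect_equal(lr_schedule(1), 0.1)
  expect_equal(lr_schedule(26), 0.01)
  expect_equal(lr_schedule(37), 0.01)
  expect_equal(lr_schedule(38), 0.001)
  expect_equal(lr_schedule(40), 0.001)
  expect_equal(lr_schedule(45), 0.001)
  expect_equal(lr_schedule(46), 1e-4)
  rates <- vapply(1:60, lr_schedule, 0)
  expect_true(all(diff(rates) <= 0))
  expect_error(lr_schedule(0), "epoch")
  expect_error(lr_schedule(61), "epoch")
})

test_that("softmax probabilities normalize, stay in (0,1) and shift-invariance holds", {
  expect_equal(softmax_prob(rep(1.3, 5)), rep(0.2, 5))
  expect_equal(softmax_prob(c(0, log(3))), c(0.25, 0.75))
  set.seed(6)
  for (rep in 1:10) {
    s <- rnorm(4, sd = 10)
    p <- softmax_prob(s)
    expect_equal(sum(p), 1)
    expect_true(all(p > 0 & p < 1))
    expect_equal(softmax_prob(s + 123.4), p)
  }
  # max-shift keeps huge scores finite
  expect_equal(sum(softmax_prob(c(1e4, 1e4 - 5))), 1)
})

test_that("training reduces the loss, is seed-reproducible, and freezing holds the backbone", {
  cfg <- generator_config(image_size = 64L)
  set.seed(77)
  grades <- sample(c(rep(0L, 30), sample(1:4, 30, replace = TRUE)))
  ds <- generate_dataset(60, cfg, seed = 404, grades = grades)
  labels <- ifelse(ds$labels == 0, "healthy", "lesion")
  tc <- train_config(epochs = 3, seed = 5, lr_scale = 0.3, batch_size = 16)
  m1 <- train_classifier(list(images = ds$images, labels = labels), tc)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])

  m2 <- train_classifier(list(images = ds$images, labels = labels), tc)
  expect_identical(m1$class_weights, m2$class_weights)
  expect_identical(m1$params$conv[[1]]$W, m2$params$conv[[1]]$W)

  tcf <- train_config(epochs = 2, seed = 5, lr_scale = 0.3, batch_size = 16,
                      freeze_backbone = TRUE)
  mf <- train_classifier(list(images = ds$images, labels = labels), tcf)
  set.seed(tcf$seed)
  init <- fundusWSSH:::init_backbone(2L, 3L, tcf$channels, tcf$pool_after)
  expect_identical(mf$params$conv[[1]]$W, init$conv[[1]]$W)
  expect_false(identical(mf$params$head$W, init$head$W))

  expect_error(train_classifier(list(images = ds$images[1:4],
                                     labels = rep("a", 4))),
               "two classes")
})

test_that("backbone conv/backward agree with a numerical gradient", {
  set.seed(8)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  params <- fundusWSSH:::init_backbone(2L, 2L, c(4L, 4L), pool_after = 1L)
  loss_of <- function(p) {
    fwd <- fundusWSSH:::backbone_forward(p, x, training = TRUE)
    pr <- apply(fwd$scores, 2, softmax_prob)
    -mean(log(pr[1, ]))
  }
  fwd <- fundusWSSH:::backbone_forward(params, x, training = TRUE)
  pr <- apply(fwd$scores, 2, softmax_prob)
  y <- matrix(0, 2, 3); y[1, ] <- 1
  grads <- fundusWSSH:::backbone_backward(params, fwd, (pr - y) / 3)
  eps <- 1e-5
  for (probe in list(c(1, 1), c(5, 2), c(9, 3))) {
    p2 <- params
    p2$conv[[1]]$W[probe[1], probe[2]] <- p2$conv[[1]]$W[probe[1], probe[2]] + eps
    num <- (loss_of(p2) - loss_of(params)) / eps
    expect_equal(grads$conv[[1]]$W[probe[1], probe[2]], num, tolerance = 1e-3)
  }
})
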