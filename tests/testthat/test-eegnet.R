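test_that("softmax output is a probability vector", {
  cfg <- small_net_config()
  m <- eegnet_build(cfg)
  set.seed(1)
  x <- array(rnorm(5 * 9 * 96), c(5, 9, 96))
  p <- predict(m, x, type = "prob")
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
})

test_that("untrained model sits at chance on balanced data", {
  m <- eegnet_build(small_net_config())
  set.seed(2)
  x <- array(rnorm(200 * 9 * 96), c(200, 9, 96))
  y <- rep(c("class1", "class2"), 100)
  acc <- mean(predict(m, x) == y)
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / 200) + 1e-9)
})

test_that("input gradient matches central finite differences", {
  m <- eegnet_build(small_net_config())
  set.seed(3)
  x <- matrix(rnorm(9 * 96), 9)
  g <- input_gradient(m, x, 1)
  expect_equal(dim(g$gradient), dim(x))
  h <- 1e-3
  cells <- cbind(sample(9, 50, TRUE), sample(96, 50, TRUE))
  for (k in 1:50) {
    xp <- x; xp[cells[k, 1], cells[k, 2]] <- x[cells[k, 1], cells[k, 2]] + h
    xm <- x; xm[cells[k, 1], cells[k, 2]] <- x[cells[k, 1], cells[k, 2]] - h
    fd <- (input_gradient(m, xp, 1)$logits[1] -
           input_gradient(m, xm, 1)$logits[1]) / (2 * h)
    expect_equal(g$gradient[cells[k, 1], cells[k, 2]], fd,
                 tolerance = 1e-3)
  }
})

test_that("a linear network has an input-independent gradient", {
  cfg <- small_net_config(activation = "linear")
  m <- eegnet_build(cfg)
  set.seed(4)
  g1 <- input_gradient(m, matrix(rnorm(9 * 96), 9), 2)$gradient
  g2 <- input_gradient(m, matrix(rnorm(9 * 96) * 10, 9), 2)$gradient
  expect_equal(g1, g2, tolerance = 1e-10)
})

test_that("training is deterministic under a fixed seed", {
  set.seed(5)
  x <- array(rnorm(24 * 9 * 96), c(24, 9, 96))
  y <- rep(c("a", "b"), 12)
  cfg <- small_net_config(dropout = 0.2, n_epochs = 3)
  m1 <- eegnet_train(cfg, x, y)
  m2 <- eegnet_train(cfg, x, y)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("the network has capacity for a separable toy problem", {
  set.seed(6)
  n <- 40
  x <- array(rnorm(n * 9 * 96) * 0.1, c(n, 9, 96))
  x[1:(n / 2), 3, ] <- x[1:(n / 2), 3, ] +
    2 * sin(seq(0, 6 * pi, length.out = 96))
  y <- rep(c("on", "off"), each = n / 2)
  cfg <- small_net_config(dropout = 0.1, n_epochs = 30,
                          batch_size = 8)
  m <- eegnet_train(cfg, x, y)
  expect_equal(mean(predict(m, x) == y), 1)
})

test_that("standardization statistics come from the training data only", {
  set.seed(7)
  x <- array(rnorm(20 * 9 * 96, mean = 5, sd = 2), c(20, 9, 96))
  y <- rep(c("a", "b"), 10)
  m <- eegnet_train(small_net_config(n_epochs = 1), x, y)
  expect_equal(m$standardize$mu, apply(x, 2, mean))
  expect_equal(m$standardize$sd, apply(x, 2, sd))
})

test_that("invalid training inputs are rejected", {
  set.seed(8)
  x <- array(rnorm(10 * 9 * 96), c(10, 9, 96))
  expect_error(eegnet_train(small_net_config(), x, rep("a", 10)),
               "single class")
  expect_error(eegnet_train(small_net_config(), x[, 1:3, ], rep(c("a", "b"), 5)),
               "shape")
  m <- eegnet_build(small_net_config())
  expect_error(input_gradient(m, matrix(0, 9, 96), "nope"), "unknown class")
  expect_error(eegnet_config(9, 96, 2, srate = 64, temporal_kernel = 200),
               "longer")
})
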