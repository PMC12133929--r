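test_that("identical seeds give bit-identical recordings", {
  s1 <- simulate_var(base_var3(seed = 7))
  s2 <- simulate_var(base_var3(seed = 7))
  expect_identical(s1$signal, s2$signal)
  s3 <- simulate_var(base_var3(seed = 8))
  expect_false(identical(s1$signal, s3$signal))
})

test_that("zero-coefficient process is independent white noise", {
  spec <- var_spec(3, 1, coeffs = array(0, c(1, 3, 3)), n_samples = 20000,
                   seed = 2)
  rec <- simulate_var(spec)
  for (lag in 0:3) {
    cc <- cor(rec$signal[1, 1:(20000 - lag)], rec$signal[2, (1 + lag):20000])
    expect_lt(abs(cc), 0.03)
  }
})

test_that("AR(1) sample variance matches the closed form sigma^2/(1-a^2)", {
  spec <- var_spec(1, 1, coeffs = array(0.9, c(1, 1, 1)),
                   n_samples = 100000, seed = 5)
  rec <- simulate_var(spec)
  expect_equal(var(rec$signal[1, ]), 1 / (1 - 0.81), tolerance = 0.05)
})

test_that("non-stationary coefficients are rejected with the spectral radius", {
  expect_error(var_spec(2, 1, coeffs = array(diag(1.05, 2), c(1, 2, 2)),
                        n_samples = 100),
               "spectral radius")
  expect_error(var_spec(1, 50, coeffs = array(0, c(50, 1, 1)),
                        n_samples = 40),
               "order")
})

test_that("switching dataset is balanced with the planted mask and context", {
  sp <- switching_spec(base_var3(), planted_pair = c(1, 2),
                       coupling_gain = 0.8, active_window = c(33, 97),
                       epoch_length = 128, n_epochs_per_class = 10,
                       context_samples = 8, seed = 3)
  ds <- make_switching_dataset(sp)
  expect_equal(n_epochs(ds$epochs), 20)
  expect_equal(unname(table(ds$epochs$labels)), c(10L, 10L),
               ignore_attr = TRUE)
  expect_equal(ds$epochs$context, 8L)
  expect_equal(dim(ds$epochs$data), c(20, 3, 136))
  # mask is 1 exactly on the planted pair inside the active window
  expect_equal(sum(ds$ground_truth), 97 - 33)
  expect_true(all(ds$ground_truth[1, 2, 33:96] == 1))
  expect_true(all(ds$ground_truth[-1, , ] == 0))
  expect_true(all(ds$ground_truth[, -2, ] == 0))
  # reproducible
  ds2 <- make_switching_dataset(sp)
  expect_identical(ds$epochs$data, ds2$epochs$data)
})

test_that("destabilizing coupling gain is rejected", {
  # instability needs a feedback loop: base already couples 2 <- 1, and the
  # planted 1 <- 2 gain closes the cycle
  cf <- array(diag(0.5, 3), c(1, 3, 3)); cf[1, 2, 1] <- 0.6
  fb <- var_spec(3, 1, coeffs = cf, n_samples = 136, srate = 64)
  expect_error(switching_spec(fb, planted_pair = c(1, 2), coupling_gain = 5,
                              active_window = c(33, 97)),
               "non-stationary")
  expect_error(switching_spec(base_var3(), planted_pair = c(2, 2)),
               "distinct")
  expect_error(switching_spec(base_var3(), active_window = c(100, 90)),
               "active_window")
})

test_that("coupled epochs carry extra energy only inside the active window", {
  sp <- switching_spec(base_var3(), planted_pair = c(1, 2),
                       coupling_gain = 0.8, active_window = c(33, 97),
                       epoch_length = 128, n_epochs_per_class = 30,
                       context_samples = 8, seed = 9)
  ds <- make_switching_dataset(sp)
  co <- ds$epochs$labels == "coupled"
  win <- 8 + (33:96)          # context offset
  pre <- 8 + (1:32)
  v_in <- mean(ds$epochs$data[co, 1, win]^2) /
    mean(ds$epochs$data[!co, 1, win]^2)
  v_out <- mean(ds$epochs$data[co, 1, pre]^2) /
    mean(ds$epochs$data[!co, 1, pre]^2)
  expect_gt(v_in, 1.5)        # coupling raises channel-1 variance in window
  expect_lt(abs(v_out - 1), 0.5)
})
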