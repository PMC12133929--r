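test_that("reconstruction identity holds to machine precision", {
  set.seed(1)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000))
  f <- fit_ar(x, 5)
  xc <- x - f$mean
  lagpred <- sapply(1:5, function(n) xc[f$t_valid - n]) %*% f$coef
  expect_lt(max(abs(xc[f$t_valid] - lagpred - f$innovations)), 1e-10)
})

test_that("white-noise fit has near-zero coefficients and preserved variance", {
  set.seed(2)
  x <- rnorm(50000)
  f <- fit_ar(x, 20)
  expect_true(all(abs(f$coef) < 0.05))
  expect_equal(f$sigma2, var(x), tolerance = 0.02)
})

test_that("AR(2) coefficients are recovered on a long simulation", {
  set.seed(3)
  x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 50000))
  f <- fit_ar(x, 2)
  expect_lt(max(abs(f$coef - c(0.5, -0.3))), 0.02)
})

test_that("influence regression recovers a planted lag coefficient", {
  set.seed(4)
  T_ <- 50000 + 20
  xj <- as.numeric(arima.sim(list(ar = 0.4), T_))
  t_valid <- 21:T_
  eps <- 0.8 * xj[t_valid - 3] + rnorm(length(t_valid))
  g <- fit_influence(eps, xj, 20, t_valid)
  expect_equal(g$coef[3], 0.8, tolerance = 0.02)
  expect_true(all(abs(g$coef[-3]) < 0.05))
})

test_that("chance-level influence fit reduces variance by less than N/n", {
  set.seed(5)
  T_ <- 50020
  xj <- rnorm(T_)
  eps <- rnorm(50000)
  g <- fit_influence(eps, xj, 20, 21:T_)
  reduction <- 1 - g$sigma2 / mean(eps^2)
  expect_lt(reduction, 0.001)
})

test_that("influence signal identities are definitional", {
  eps <- rnorm(100); res <- rnorm(100)
  expect_equal(influence_signal(eps, eps), rep(0, 100))
  expect_equal(influence_signal(eps, rep(0, 100)), eps)
  c_ <- influence_signal(eps, res)
  expect_equal(c_ + res, eps, tolerance = 1e-15)
  expect_error(influence_signal(eps, res[-1]), "length")
})

test_that("granger_causality matches analytic values and rejects bad input", {
  expect_equal(granger_causality(2, 2), 0)
  expect_equal(granger_causality(exp(1) * 3, 3), 1)
  expect_error(granger_causality(0, 1), "positive")
  expect_error(granger_causality(1, -2), "positive")
})

test_that("GC detects the simulated coupling direction and not its reverse", {
  cp <- coupled_pair(20000, gain = 0.5, seed = 6)
  N <- 4
  fi <- fit_ar(cp$xi, N)
  gi <- fit_influence(fi$innovations, cp$xj, N, fi$t_valid)
  fj <- fit_ar(cp$xj, N)
  gj <- fit_influence(fj$innovations, cp$xi, N, fj$t_valid)
  expect_gt(granger_causality(fi$sigma2, gi$sigma2), 0.05)
  expect_lt(granger_causality(fj$sigma2, gj$sigma2), 0.01)
})

test_that("didi fit satisfies both identities and in-sample monotonicity", {
  for (seed in 1:3) {
    rec <- simulate_var(base_var3(n_samples = 400, seed = seed))
    fit <- didi(rec, order = 6)
    M <- 3
    eps <- residuals(fit)
    infl <- inflated(fit)$data
    for (i in 1:M) {
      expect_equal(infl[i, i, ], eps[i, ], tolerance = 1e-12)
      for (j in setdiff(1:M, i)) {
        eps_ij <- eps[i, ] - infl[i, j, ]     # identity: eps = c + eps_ij
        expect_lte(mean(eps_ij^2), fit$ar$sigma2[i] + 1e-12)
      }
    }
    gcm <- gc_matrix(fit)
    expect_true(all(gcm >= -1e-12, na.rm = TRUE))
  }
})

test_that("output length follows the context convention", {
  set.seed(7)
  x <- matrix(rnorm(2 * 300), 2)
  f_nc <- didi(x, order = 10)                    # no context: T' = T - N
  expect_equal(f_nc$n_fitted, 290)
  f_c <- didi(x, order = 10, context = 10)       # N context: T' = T - N too,
  expect_equal(f_c$n_fitted, 290)                # context consumed from T
  ie <- inflate_epoch(x, order = 10, context = 10)
  expect_equal(dim(ie$data)[3], 290)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_ar(rnorm(5), 10), "too short")
  x <- matrix(c(rnorm(100), rep(1, 100)), 2, byrow = TRUE)
  rownames(x) <- c("good", "flat")
  expect_error(didi(x, order = 3), "flat")
  expect_error(fit_influence(rnorm(10), rnorm(30), 4, 3:12),
               "history")
})

test_that("inflated epoch has M*M components with quiet off-diagonals on white noise", {
  set.seed(8)
  x <- matrix(rnorm(19 * 1004), 19)
  ie <- inflate_epoch(x, order = 4, context = 4)
  expect_equal(dim(ie$data)[1:2], c(19, 19))
  expect_equal(nrow(flatten(ie)), 361)
  for (i in c(1, 7, 19)) {
    vdiag <- mean(ie$data[i, i, ]^2)
    for (j in setdiff(c(2, 11), i))
      expect_lt(mean(ie$data[i, j, ]^2), 0.01 * vdiag)
  }
})

test_that("per-recording models applied to epochs keep the decomposition identity", {
  rec <- simulate_var(base_var3(n_samples = 2000, seed = 10))
  fit <- didi(rec, order = 6, scope = "recording")
  epoch <- rec$signal[, 501:700]
  ie <- predict(fit, epoch, context = 6)
  expect_equal(dim(ie$data), c(3, 3, 194))
  # diagonal = innovations from the stored univariate coefficients
  mu <- rowMeans(epoch[, 7:200])
  xc <- epoch - mu
  i <- 1
  pred <- sapply(1:6, function(n) xc[i, (7:200) - n]) %*% fit$ar$coef[i, ]
  expect_equal(ie$data[i, i, ], as.numeric(xc[i, 7:200] - pred),
               tolerance = 1e-12)
})

test_that("summary, coef and print methods expose the fit", {
  rec <- simulate_var(base_var3(n_samples = 300, seed = 11))
  fit <- didi(rec, order = 4)
  s <- summary(fit)
  expect_s3_class(s, "summary.didi")
  expect_equal(dim(s$gc), c(3, 3))
  cf <- coef(fit)
  expect_equal(dim(cf$ar), c(3, 4))
  expect_equal(dim(cf$influence), c(3, 3, 4))
  expect_output(print(fit), "didi")
  expect_output(print(s), "Granger")
})
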