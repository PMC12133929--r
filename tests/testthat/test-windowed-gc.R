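test_that("window count follows floor((T - window)/step) + 1", {
  set.seed(1)
  x <- rnorm(800); y <- rnorm(800)
  w <- suppressWarnings(windowed_gc(x, y, order = 8, window_samples = 160,
                                    step_samples = 160))
  expect_equal(nrow(w), 5)
  expect_equal(w$center[1], 1 + 159 / 2)
  w2 <- suppressWarnings(windowed_gc(x, y, order = 8, window_samples = 100,
                                     step_samples = 50))
  expect_equal(nrow(w2), floor((800 - 100) / 50) + 1)
})

test_that("short windows warn and oversized windows error", {
  set.seed(2)
  x <- rnorm(400); y <- rnorm(400)
  expect_warning(windowed_gc(x, y, 20, 100, 100), "10x")
  expect_error(suppressWarnings(windowed_gc(x, y, 4, 500, 100)), "longer")
})

test_that("windowed GC estimator variance shrinks as the window grows", {
  # stationary coupled pair; variance of per-window estimates should fall
  # monotonically over increasing window sizes (20 simulations)
  vars <- sapply(1:20, function(s) {
    cp <- coupled_pair(1200, gain = 0.5, seed = 100 + s)
    sapply(c(80, 120, 160), function(w)
      var(suppressWarnings(
        windowed_gc(cp$xi, cp$xj, 8, w, 40))$gc))
  })
  m <- rowMeans(vars)
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("null pair windowed GC is small, nonnegative, below a permutation null", {
  set.seed(3)
  x <- rnorm(800); y <- rnorm(800)
  obs <- suppressWarnings(windowed_gc(x, y, 4, 160, 80))
  expect_true(all(obs$gc >= -1e-12))
  perm_med <- sapply(1:49, function(k) {
    set.seed(1000 + k)
    median(suppressWarnings(windowed_gc(x, sample(y), 4, 160, 80))$gc)
  })
  expect_lte(median(obs$gc), quantile(perm_med, 0.95) + 1e-9)
})
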