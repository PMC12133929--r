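# small trained-ish fixture: untrained net over a 3-channel inflated input
make_sal <- function(values = NULL, M = 3, Tn = 96) {
  m <- eegnet_build(small_net_config(n_channels = M * M, n_samples = Tn))
  set.seed(1)
  x <- matrix(rnorm(M * M * Tn), M * M)
  s <- saliency_map(m, x, target_class = 1)
  if (!is.null(values)) s$values <- values
  s
}

test_that("saliency is the gradient magnitude and sign-flip invariant", {
  m <- eegnet_build(small_net_config(n_channels = 9, n_samples = 96))
  set.seed(2)
  x <- matrix(rnorm(9 * 96), 9)
  s_abs <- saliency_map(m, x, target_class = 1)
  s_sgn <- saliency_map(m, x, target_class = 1, signed = TRUE)
  expect_true(all(s_abs$values >= 0))
  expect_equal(abs(s_sgn$values), s_abs$values)
  g <- input_gradient(m, x, 1, scale = "input")$gradient
  expect_equal(s_abs$values, abs(g), ignore_attr = TRUE)
})

test_that("zero parameters give an all-zero saliency map", {
  m <- eegnet_build(small_net_config(n_channels = 9, n_samples = 96))
  m$params <- lapply(m$params, function(p) { p[] <- 0; p })
  s <- saliency_map(m, matrix(rnorm(9 * 96), 9), target_class = 1)
  expect_true(all(s$values == 0))
})

test_that("support_at and support_avg reorder columns into squares", {
  s <- make_sal()
  sa <- support_at(s, 5)
  expect_equal(dim(sa), c(3, 3))
  expect_equal(unclass(sa), unflatten_column(s$values[, 5], 3),
               ignore_attr = TRUE)
  # single-column interval equals support_at
  expect_equal(unclass(support_avg(s, 5, 6)), unclass(sa),
               ignore_attr = TRUE)
  # full-range average equals temporal mean then unflatten
  full <- support_avg(s)
  expect_equal(unclass(full), unflatten_column(rowMeans(s$values), 3),
               ignore_attr = TRUE, tolerance = 1e-15)
})

test_that("support_avg is linear in the saliency values", {
  s1 <- make_sal()
  s2 <- make_sal()
  set.seed(3)
  s2$values <- matrix(runif(length(s2$values)), nrow(s2$values))
  s_sum <- s1; s_sum$values <- s1$values + 2 * s2$values
  lhs <- unclass(support_avg(s_sum, 10, 40))
  rhs <- unclass(support_avg(s1, 10, 40)) + 2 * unclass(support_avg(s2, 10, 40))
  expect_equal(lhs, rhs, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant saliency gives a uniform support matrix", {
  s <- make_sal(values = matrix(0.7, 9, 96))
  expect_equal(unclass(support_avg(s)), matrix(0.7, 3, 3),
               ignore_attr = TRUE)
})

test_that("interval and index bounds are enforced", {
  s <- make_sal()
  expect_error(support_at(s, 0), "out of range")
  expect_error(support_at(s, 97), "out of range")
  expect_error(support_avg(s, 10, 10), "empty|interval")
  expect_error(support_avg(s, 0, 5), "interval")
})

test_that("rendering draws one arrow per displayed connection, deterministically", {
  ch <- c("Fz", "Cz", "Pz")
  m <- matrix(0, 3, 3, dimnames = list(ch, ch))
  m[1, 2] <- 1
  f1 <- tempfile(fileext = ".png"); f2 <- tempfile(fileext = ".png")
  a1 <- render_support_map(m, top_k = 5, file = f1)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$from, "Cz"); expect_equal(a1$to, "Fz")
  a2 <- render_support_map(m, top_k = 5, file = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # all-zero matrix: no arrows
  z <- matrix(0, 3, 3, dimnames = list(ch, ch))
  fz <- tempfile(fileext = ".png")
  expect_equal(nrow(render_support_map(z, file = fz)), 0)
  # unknown electrode errors with its name
  bad <- matrix(1, 2, 2, dimnames = list(c("Fz", "XX"), c("Fz", "XX")))
  expect_error(render_support_map(bad, file = tempfile(fileext = ".png")),
               "XX")
})

test_that("frame export writes one comparable frame per (strided) sample", {
  s <- make_sal()
  s$channel_names <- c("Fz", "Cz", "Pz")
  d <- tempfile()
  files <- export_frames(s, dir = d, stride = 16)
  expect_equal(length(files), length(seq(1, 96, by = 16)))
  expect_true(all(file.exists(files)))
})

test_that("support matrices average across epochs and export to CSV", {
  s <- make_sal()
  m1 <- support_avg(s); m2 <- support_avg(s, 1, 10)
  mm <- support_mean(list(m1, m2))
  expect_equal(unclass(mm), (unclass(m1) + unclass(m2)) / 2,
               ignore_attr = TRUE)
  f <- tempfile(fileext = ".csv")
  write_support_csv(mm, f)
  back <- read.csv(f, row.names = 1)
  expect_equal(as.matrix(back), unclass(mm), ignore_attr = TRUE,
               tolerance = 1e-10)
})
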