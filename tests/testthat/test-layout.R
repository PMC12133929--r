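test_that("row order is influenced-major", {
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- 11; arr[1, 2, ] <- 12; arr[2, 1, ] <- 21; arr[2, 2, ] <- 22
  fl <- flatten(arr)
  expect_equal(fl[, 1], c(11, 12, 21, 22), ignore_attr = TRUE)
  expect_equal(row_of(2, 1, 2), 3)
  expect_equal(pair_of(3, 2), list(i = 2L, j = 1L))
})

test_that("flatten/unflatten is an exact bijection across M", {
  for (M in c(2, 3, 19)) {
    set.seed(M)
    arr <- array(rnorm(M * M * 5), c(M, M, 5))
    fl <- flatten(arr)
    expect_equal(nrow(fl), M * M)
    for (t in c(1, 5)) {
      back <- unflatten_column(fl[, t], M)
      expect_identical(back, arr[, , t])
    }
    # full round trip through the index map
    p <- pair_of(seq_len(M * M), M)
    expect_equal(row_of(p$i, p$j, M), seq_len(M * M))
  }
})

test_that("a 19-channel inflated epoch flattens to 361 classifier rows", {
  expect_equal(nrow(pair_index_map(19)), 361)
})

test_that("bad indices and lengths are rejected", {
  expect_error(unflatten_column(rep(1, 5), 2), "M\\^2")
  expect_error(row_of(3, 1, 2), "out of range")
  expect_error(pair_of(5, 2), "out of range")
  expect_equal(unflatten_column(rep(1, 4), 2), matrix(1, 2, 2))
})

test_that("index map sidecar is decodable JSON with channel names", {
  f <- tempfile(fileext = ".json")
  write_index_map(3, c("Fz", "Cz", "Pz"), f)
  m <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(m$M, 3)
  expect_equal(nrow(m$rows), 9)
  expect_equal(m$rows$influenced[4], "Cz")   # row 4 = (2 <- 1)
  expect_equal(m$rows$influencing[4], "Fz")
})
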