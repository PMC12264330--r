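test_that("normalization gives zero mean, unit population sd, and is idempotent", {
  x <- array(0, dim = c(8, 4, 4, 7))
  set.seed(11)
  for (c in 1:7) x[, , , c] <- rnorm(8 * 16, mean = c, sd = c)
  vol <- normalize_volume(image_volume(x))
  m <- matrix(vol$data, ncol = 7)
  expect_true(all(abs(colMeans(m)) < 1e-6))
  expect_true(all(abs(sqrt(colMeans(m^2) - colMeans(m)^2) - 1) < 1e-6))
  again <- normalize_volume(vol)
  expect_lt(max(abs(again$data - vol$data)), 1e-6)
})

test_that("z-scoring a 3-value channel matches hand arithmetic (population sd)", {
  x <- array(rnorm(6 * 4 * 4 * 7), dim = c(6, 4, 4, 7))
  x[, , , 1] <- rep(c(1, 2, 3), length.out = 6 * 16)  # balanced counts
  vol <- normalize_volume(image_volume(x))
  got <- sort(unique(as.vector(round(vol$data[, , , 1], 4))))
  expect_equal(got, c(-1.2247, 0, 1.2247))
})

test_that("constant channels are rejected as degenerate", {
  x <- array(rnorm(8 * 4 * 4 * 7), dim = c(8, 4, 4, 7))
  x[, , , 3] <- 5
  expect_error(normalize_volume(image_volume(x)), "degenerate")
})

test_that("one-hot encode/decode round-trips every {0,1,2} grid", {
  set.seed(7)
  cm <- array(sample(0:2, 64, replace = TRUE), dim = c(4, 4, 4))
  mask <- onehot_encode(cm)
  sums <- apply(mask$onehot, 1:3, sum)
  expect_true(all(sums == 1))
  expect_identical(onehot_decode(mask), cm)
  expect_equal(unname(mask$onehot[1, 1, 1, ]),
               as.numeric(0:2 == cm[1, 1, 1]))
  allbg <- onehot_encode(array(2L, dim = c(2, 3, 3)))
  expect_true(all(allbg$onehot[, , , 3] == 1))
  expect_error(onehot_encode(array(3L, dim = c(2, 2, 2))), "values")
})

test_that("window enumeration follows the first/last-eight rule", {
  expect_identical(enumerate_windows(8), 0L)
  expect_identical(enumerate_windows(12), c(0L, 4L))
  expect_identical(enumerate_windows(16), c(0L, 8L))
  expect_error(enumerate_windows(7), "at least 8")
  expect_error(enumerate_windows(17), "cannot cover")
  for (n in 8:16) {
    starts <- enumerate_windows(n)
    cover <- integer(n)
    for (s in starts) cover[(s + 1):(s + 8)] <- cover[(s + 1):(s + 8)] + 1L
    expect_true(all(cover >= 1) && all(cover <= 2))
  }
  starts <- enumerate_windows(27, mode = "permissive")
  cover <- integer(27)
  for (s in starts) cover[(s + 1):(s + 8)] <- cover[(s + 1):(s + 8)] + 1L
  expect_true(all(cover >= 1))
})

test_that("NIfTI round-trip preserves class maps, channels and spacing", {
  dir <- withr::local_tempdir()
  rec <- generate_phantom(tiny_phantom_config(seed = 3, H = 16, W = 16),
                          id = "rt")
  ip <- file.path(dir, "rt.nii.gz")
  lp <- file.path(dir, "rt_label.nii.gz")
  write_volume(rec$volume, ip)
  write_mask(rec$label, lp, spacing = rec$volume$spacing)
  back <- read_volume(ip, label_path = lp)
  expect_identical(onehot_decode(back$label), onehot_decode(rec$label))
  expect_equal(back$volume$spacing, c(2, 0.31, 0.31), tolerance = 1e-5)
  expect_equal(dim(back$volume$data), dim(rec$volume$data))

  bad <- file.path(dir, "bad.nii.gz")
  img5 <- RNifti::asNifti(array(0, dim = c(8, 16, 16, 5)))
  RNifti::writeNifti(img5, bad)
  expect_error(read_volume(bad), "7 contrast channels")
})

test_that("windows crop image and label consistently", {
  rec <- generate_phantom(tiny_phantom_config(seed = 5, H = 16, W = 16))
  # duplicate slices to build a 12-slice volume
  x <- rec$volume$data[c(1:8, 5:8), , , , drop = FALSE]
  oh <- rec$label$onehot[c(1:8, 5:8), , , , drop = FALSE]
  vol <- image_volume(x)
  lab <- label_mask(oh)
  w <- extract_window(vol, 4, lab)
  expect_identical(w$data, x[5:12, , , , drop = FALSE])
  expect_identical(w$label, oh[5:12, , , , drop = FALSE])
  expect_identical(w$quality, "well_registered")
})
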