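test_that("the noiseless limit reduces to a pure geometry image", {
  cfg <- tiny_phantom_config(seed = 2, noise_sd = 1e-12, texture_sd = 0)
  rec <- generate_phantom(cfg, normalize = FALSE)
  cm <- onehot_decode(rec$label)
  # channel 1 separates the classes: thresholding it reproduces the label
  ch <- rec$volume$data[, , , 1]
  means <- default_channel_means()[, 1]
  recovered <- array(apply(abs(outer(as.vector(ch), means, "-")), 1,
                           which.min) - 1L, dim = dim(cm))
  expect_identical(recovered, cm)
})

test_that("lumen voxel count per slice matches the disk area within discretization error", {
  cfg <- tiny_phantom_config(seed = 4)
  rec <- generate_phantom(cfg)
  cm <- onehot_decode(rec$label)
  r <- cfg$lumen_radius
  for (s in 1:dim(cm)[1]) {
    count <- sum(cm[s, , ] == 0)
    expect_lt(abs(count - pi * r^2), 2 * pi * r)
  }
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_phantom(tiny_phantom_config(seed = 9))
  b <- generate_phantom(tiny_phantom_config(seed = 9))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$label$onehot, b$label$onehot)
  c <- generate_phantom(tiny_phantom_config(seed = 10))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("zero-shift corruption is the identity on the mask", {
  rec <- generate_phantom(tiny_phantom_config(seed = 1))
  spec <- misalignment_spec(shift = c(0, 0), sector = c(0, 180))
  out <- corrupt_label(rec$label, spec)
  expect_identical(out$onehot, rec$label$onehot)
  expect_identical(out$quality, "misaligned")
})

test_that("slice_shift preserves foreground count and leaves other slices untouched", {
  rec <- generate_phantom(tiny_phantom_config(seed = 6))
  spec <- misalignment_spec(mode = "slice_shift", shift = c(3, 0),
                            affected_slices = 2L)
  out <- corrupt_label(rec$label, spec)
  cm0 <- onehot_decode(rec$label)
  cm1 <- onehot_decode(out)
  expect_equal(sum(cm1[3, , ] < 2), sum(cm0[3, , ] < 2))
  expect_identical(cm1[-3, , ], cm0[-3, , ])
})

test_that("sector displacement corrupts only affected slices and stays one-hot", {
  rec <- generate_phantom(tiny_phantom_config(seed = 8))
  spec <- misalignment_spec(mode = "sector_displace", shift = c(2, 2),
                            sector = c(90, 180), affected_slices = c(1L, 4L))
  out <- corrupt_label(rec$label, spec)
  sums <- apply(out$onehot, 1:3, sum)
  expect_true(all(sums == 1))
  cm0 <- onehot_decode(rec$label)
  cm1 <- onehot_decode(out)
  for (s in c(2, 5)) {
    expect_lt(dsc(cm1[s, , ] == 1, cm0[s, , ] == 1), 100)
  }
  for (s in c(1, 3, 4, 6, 7, 8)) {
    expect_identical(cm1[s, , ], cm0[s, , ])
  }
})

test_that("larger sectors change more of the boundary; larger shifts lower wall Dice", {
  rec <- generate_phantom(tiny_phantom_config(seed = 12))
  cm0 <- onehot_decode(rec$label)
  changed <- vapply(c(45, 90, 180), function(span) {
    out <- corrupt_label(rec$label, misalignment_spec(
      shift = c(3, 0), sector = c(0, span), affected_slices = 0:7))
    sum(onehot_decode(out) != cm0)
  }, 0)
  expect_true(all(diff(changed) > 0))

  dices <- vapply(1:4, function(mag) {
    out <- corrupt_label(rec$label, misalignment_spec(
      shift = c(mag, 0), sector = c(0, 120), affected_slices = 0:7))
    dsc(onehot_decode(out) == 1, cm0 == 1)
  }, 0)
  expect_true(all(diff(dices) < 0))
})

test_that("dataset generation writes a coherent manifest with hidden clean labels", {
  dir <- withr::local_tempdir()
  cfg <- tiny_phantom_config(H = 16, W = 16)
  manifest <- generate_dataset(2, 2, cfg, seed = 42, out_dir = dir)
  expect_equal(nrow(manifest), 4)
  expect_equal(sum(manifest$quality == "misaligned"), 2)
  mis <- manifest[manifest$quality == "misaligned", ]
  for (i in seq_len(nrow(mis))) {
    clean_path <- file.path(dir, paste0(mis$volume_id[i], "_clean.nii.gz"))
    expect_true(file.exists(clean_path))
    served <- as.array(RNifti::readNifti(file.path(dir, mis$label_path[i])))
    clean <- as.array(RNifti::readNifti(clean_path))
    expect_false(identical(served, clean))
  }
  # regeneration with the same master seed is byte-identical
  dir2 <- withr::local_tempdir()
  generate_dataset(2, 2, cfg, seed = 42, out_dir = dir2)
  for (i in seq_len(nrow(manifest))) {
    a <- as.array(RNifti::readNifti(file.path(dir, manifest$label_path[i])))
    b <- as.array(RNifti::readNifti(file.path(dir2, manifest$label_path[i])))
    expect_identical(dim(a), dim(b))
    expect_identical(as.vector(a), as.vector(b))
  }
  ds <- load_dataset(read_manifest(file.path(dir, "manifest.csv")))
  expect_length(ds$train, 4)
  expect_s3_class(ds$train[[1]]$volume, "image_volume")
})
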