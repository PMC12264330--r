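test_that("fused prediction equals the window-wise average of model probabilities", {
  arch <- tiny_arch()
  pair <- model_pair(arch, seed = 4)
  # make teacher differ from student
  stu2 <- build_model(arch, seed = 9)$params
  pair$teacher$params <- ema_update(pair$teacher$params, stu2, alpha = 0.5)

  rec <- generate_phantom(tiny_phantom_config(seed = 2, H = 16, W = 16))
  x12 <- rec$volume$data[c(1:8, 5:8), , , , drop = FALSE]
  vol <- image_volume(x12, id = "v12")
  res <- predict_volume(pair, vol, fuse_teacher = TRUE)

  fuse_window <- function(s) {
    wdw <- extract_window(vol, s)
    (unet_forward(pair$student, wdw$data)$probs +
       unet_forward(pair$teacher, wdw$data)$probs) / 2
  }
  f0 <- fuse_window(0)
  f4 <- fuse_window(4)
  # non-overlapping slices come from a single window
  expect_equal(res$fused_probs[1:4, , , ], f0[1:4, , , ], tolerance = 1e-12)
  expect_equal(res$fused_probs[9:12, , , ], f4[5:8, , , ], tolerance = 1e-12)
  # overlap slices are the mean of the two windows
  expect_equal(res$fused_probs[5:8, , , ],
               (f0[5:8, , , ] + f4[1:4, , , ]) / 2, tolerance = 1e-12)
  # class map is the argmax of the fused probabilities
  m <- matrix(res$fused_probs, ncol = 3)
  expect_identical(as.vector(res$class_map),
                   as.vector(max.col(m, ties.method = "first") - 1L))
})

test_that("student-identical teacher makes fusion a no-op", {
  pair <- model_pair(tiny_arch(), seed = 6)
  rec <- generate_phantom(tiny_phantom_config(seed = 3, H = 16, W = 16))
  fused <- predict_volume(pair, rec$volume, fuse_teacher = TRUE)
  solo <- predict_volume(pair, rec$volume, fuse_teacher = FALSE)
  expect_equal(fused$fused_probs, solo$fused_probs, tolerance = 1e-12)
  expect_identical(fused$class_map, solo$class_map)
})

test_that("DSC matches hand-computed values and basic invariances", {
  a <- array(FALSE, dim = c(1, 10, 10)); a[1, 1:5, 1:10] <- TRUE
  expect_equal(dsc(a, a), 100)
  b <- array(FALSE, dim = c(1, 10, 10)); b[1, 6:10, 1:10] <- TRUE
  expect_equal(dsc(a, b), 0)
  # |A| = |B| = 100, |A n B| = 50 -> 66.67
  a2 <- array(FALSE, dim = c(1, 20, 10)); a2[1, 1:10, ] <- TRUE
  b2 <- array(FALSE, dim = c(1, 20, 10)); b2[1, 6:15, ] <- TRUE
  expect_equal(dsc(a2, b2), 200 * 50 / 200, tolerance = 1e-9)
  expect_equal(dsc(b2, a2), dsc(a2, b2))
  z <- array(FALSE, dim = c(1, 4, 4))
  expect_equal(dsc(z, z), 100)
  expect_equal(dsc(a[, 1:4, 1:4, drop = FALSE], z), 0)
})

test_that("surface distances match simple geometric cases", {
  z <- array(FALSE, dim = c(1, 12, 12))
  a <- z; a[1, 3, 3] <- TRUE
  b <- z; b[1, 3, 8] <- TRUE
  expect_equal(unname(surface_distances(a, a, c(1, 1, 1))), c(0, 0))
  got <- surface_distances(a, b, c(1, 1, 1))
  expect_equal(unname(got), c(5, 5))

  sq <- z; sq[1, 4:8, 4:8] <- TRUE
  sq2 <- z; sq2[1, 5:9, 4:8] <- TRUE
  got2 <- surface_distances(sq, sq2, c(1, 1, 1))
  expect_lte(got2[["asd"]], 1)
  expect_lte(got2[["hd95"]], sqrt(2))

  expect_warning(sd_na <- surface_distances(z, a, c(1, 1, 1)), "empty")
  expect_true(all(is.na(sd_na)))
})

test_that("surface distances respect anisotropic spacing", {
  z <- array(FALSE, dim = c(4, 6, 6))
  a <- z; a[1, 3, 3] <- TRUE
  b <- z; b[3, 3, 3] <- TRUE
  got <- surface_distances(a, b, spacing = c(2, 0.31, 0.31))
  expect_equal(unname(got), c(4, 4))
})

test_that("volume evaluation derives the three structures correctly", {
  rec <- generate_phantom(tiny_phantom_config(seed = 5))
  cm <- onehot_decode(rec$label)
  perfect <- evaluate_volume(cm, rec$label, spacing = c(1, 1, 1))
  expect_equal(perfect$dsc_wall, 100)
  expect_equal(perfect$dsc_lumen, 100)
  expect_equal(perfect$dsc_outer, 100)
  expect_equal(perfect$hd95_outer, 0)
  expect_equal(perfect$asd_lumen, 0)
  expect_equal(perfect$dsc_avg, 100)

  # labelling the whole outer-wall region as lumen keeps the outer wall perfect
  alllumen <- cm
  alllumen[cm == 1] <- 0L
  m <- evaluate_volume(alllumen, rec$label, spacing = c(1, 1, 1))
  expect_equal(m$dsc_outer, 100)
  expect_lt(m$dsc_lumen, 100)
  expect_equal(m$dsc_wall, 0)

  expect_equal((90 + 80) / 2, 85)
  expect_equal(m$dsc_avg, (m$dsc_lumen + m$dsc_outer) / 2)
})

test_that("Tukey HSD comparisons behave on synthetic groups", {
  set.seed(41)
  v <- rnorm(20, 80, 1)
  res <- compare_methods(list(a = v, b = v))
  expect_gt(res$p_adj[1], 0.99)

  far <- list(a = rnorm(20, 0, 0.01), b = rnorm(20, 10, 0.01))
  expect_lt(compare_methods(far)$p_adj[1], 1e-6)

  three <- list(a = rnorm(20, 0, 0.05), b = rnorm(20, 0, 0.05),
                c = rnorm(20, 5, 0.05))
  res3 <- compare_methods(three)
  sig <- res3$p_adj < 0.05
  expect_identical(grepl("c", res3$pair), sig)

  expect_error(compare_methods(list(a = 1, b = rnorm(5))), "at least 2")
})
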