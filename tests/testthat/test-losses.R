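test_that("binary Dice loss matches hand-computed cases", {
  m <- array(0, dim = c(2, 2, 2))
  m[1, 1, 1] <- 1
  expect_equal(binary_dice_loss(m, m), 0, tolerance = 1e-4)
  disj <- array(0, dim = c(2, 2, 2))
  disj[2, 2, 2] <- 1
  expect_equal(binary_dice_loss(m, disj), 1, tolerance = 1e-4)
  expect_equal(binary_dice_loss(c(1, 0), c(0.5, 0.5)), 0.5, tolerance = 1e-4)
  # empty-vs-empty is defined as 0 by smoothing
  z <- array(0, dim = c(2, 2, 2))
  expect_equal(binary_dice_loss(z, z), 0)
})

test_that("multi-class Dice averages lumen and wall and ignores background", {
  set.seed(3)
  cm <- array(sample(0:2, 4 * 4 * 4, TRUE, prob = c(.3, .3, .4)), dim = c(4, 4, 4))
  y <- onehot_encode(cm)
  expect_equal(multiclass_dice_loss(y$onehot, y), 0, tolerance = 1e-4)

  # lumen perfect, wall disjoint -> (0 + 1)/2
  p <- y$onehot
  p[, , , 2] <- y$onehot[, , , 3]  # wall prediction sits on background voxels
  p[, , , 3] <- y$onehot[, , , 2]
  expect_equal(multiclass_dice_loss(p, y), 0.5, tolerance = 1e-3)

  # uniform prediction: closed form 1 - (2/3 f)/(f + 1/3) per class, averaged
  pu <- array(1 / 3, dim = dim(y$onehot))
  f <- apply(y$onehot, 4, mean)[1:2]
  expected <- mean(1 - (2 / 3 * f) / (f + 1 / 3))
  expect_equal(multiclass_dice_loss(pu, y), expected, tolerance = 1e-4)
  expect_gte(multiclass_dice_loss(pu, y), 0)
  expect_lte(multiclass_dice_loss(pu, y), 1)
})

test_that("weighted CE matches hand arithmetic with weights (2,2,1)", {
  d <- c(1, 1, 1, 3)
  y <- array(c(1, 0, 0), dim = d)
  p <- array(c(1, 0, 0), dim = d)
  expect_equal(weighted_ce_loss(p, y), 0, tolerance = 1e-6)
  p2 <- array(c(0.5, 0.25, 0.25), dim = d)
  expect_equal(weighted_ce_loss(p2, y), -2 * log(0.5), tolerance = 1e-6)
  ysoft <- array(c(0.5, 0.5, 0), dim = d)
  p3 <- array(c(0.5, 0.5, 1e-12), dim = d)
  expect_equal(weighted_ce_loss(p3, ysoft), 2 * log(2), tolerance = 1e-6)
})

test_that("weighted CE is linear in the target and reduces to standard CE", {
  set.seed(5)
  d <- c(5, 1, 1, 3)
  p <- random_simplex(d[1:3])
  y1 <- random_simplex(d[1:3])
  y2 <- random_simplex(d[1:3])
  lam <- 0.3
  mix <- lam * y1 + (1 - lam) * y2
  expect_equal(weighted_ce_loss(p, mix),
               lam * weighted_ce_loss(p, y1) + (1 - lam) * weighted_ce_loss(p, y2),
               tolerance = 1e-10)

  # w = (1,1,1), one-hot targets: cross-validate against a scalar oracle
  true_class <- sample.int(3, 5, TRUE)
  yoh <- array(0, dim = d)
  for (i in 1:5) yoh[i, 1, 1, true_class[i]] <- 1
  expect_equal(weighted_ce_loss(p, yoh, w = c(1, 1, 1)),
               scalar_ce_onehot(matrix(p, ncol = 3), true_class),
               tolerance = 1e-10)
})

test_that("the joint fine-tuning loss is the sum of its two parts", {
  set.seed(6)
  cm <- array(sample(0:2, 8, TRUE), dim = c(2, 2, 2))
  y <- onehot_encode(cm)
  p_perfect <- y$onehot
  expect_equal(total_finetune_loss(p_perfect, y, p_perfect, y$onehot), 0,
               tolerance = 1e-4)
  p <- random_simplex(c(2, 2, 2))
  expect_equal(total_finetune_loss(p, y, p, y$onehot),
               multiclass_dice_loss(p, y) + weighted_ce_loss(p, y$onehot),
               tolerance = 1e-12)
  # with a perfect adversarial branch the joint loss equals the warm-up loss
  expect_equal(total_finetune_loss(p, y, p_perfect, y$onehot),
               multiclass_dice_loss(p, y), tolerance = 1e-6)
})
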