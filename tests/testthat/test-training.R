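make_tiny_dataset <- function(n_train = 2, n_val = 1, seed = 1, H = 16) {
  cfg <- tiny_phantom_config(seed = seed, H = H, W = H, noise_sd = 0.5)
  list(train = generate_phantom_dataset(n_train, 0, cfg, seed = seed,
                                        prefix = "tr"),
       val = generate_phantom_dataset(n_val, 0, cfg, seed = seed + 100,
                                      prefix = "va"))
}

tiny_train_config <- function(val_every = 10, ...) {
  training_config(batch_size = 2, lr = 2e-3, lr_decay_start = 1000,
                  val_every = val_every, epsilon = 0.5, seed = 1, ...)
}

test_that("window sampling is uniform over admissible starts", {
  rec <- generate_phantom(tiny_phantom_config(H = 16, W = 16))
  x <- rec$volume$data[c(1:8, 5:8), , , , drop = FALSE]
  oh <- rec$label$onehot[c(1:8, 5:8), , , , drop = FALSE]
  vol <- image_volume(x)
  lab <- label_mask(oh)
  set.seed(8)
  starts <- replicate(4000, sample_training_window(vol, lab)$start_index)
  freq <- table(factor(starts, levels = 0:4)) / 4000
  expect_true(all(abs(freq - 0.2) < 0.03))

  # N = 8 always starts at 0
  v8 <- image_volume(x[1:8, , , , drop = FALSE])
  expect_true(all(replicate(20, sample_training_window(v8, rec$label)$start_index) == 0))
})

test_that("augmentation at identity settings is a no-op and rotations involute", {
  rec <- generate_phantom(tiny_phantom_config(H = 16, W = 16))
  wdw <- extract_window(rec$volume, 0, rec$label)
  idpol <- augmentation_policy(rotate = FALSE, contrast_range = c(1, 1),
                               gamma_range = c(1, 1), hflip_prob = 0)
  out <- augment(wdw, idpol)
  expect_equal(out$data, wdw$data, tolerance = 1e-12)
  expect_identical(out$label, wdw$label)

  r180 <- vesselseg:::rot_hw(wdw$data, 2)
  expect_identical(vesselseg:::rot_hw(r180, 2), wdw$data)
  r90 <- vesselseg:::rot_hw(wdw$data, 1)
  expect_identical(vesselseg:::rot_hw(r90, 3), wdw$data)
})

test_that("augmentation keeps labels one-hot and constant channels constant", {
  rec <- generate_phantom(tiny_phantom_config(H = 16, W = 16),
                          normalize = FALSE)
  rec$volume$data[, , , 7] <- 3.14  # constant channel
  wdw <- extract_window(rec$volume, 0, rec$label)
  set.seed(4)
  out <- augment(wdw, augmentation_policy())
  sums <- apply(out$label, 1:3, sum)
  expect_true(all(sums == 1))
  expect_true(all(out$label %in% c(0, 1)))
  expect_equal(diff(range(out$data[, , , 7])), 0)
  # intensity transforms do not move the label: foreground count preserved
  expect_equal(sum(out$label[, , , 1]), sum(wdw$label[, , , 1]))
})

test_that("warm-up refuses misaligned labels and reduces the loss on easy phantoms", {
  ds <- make_tiny_dataset(n_train = 2, seed = 3)
  cfg <- tiny_train_config(iters_warmup = 40, iters_finetune = 0)
  arch <- tiny_arch()

  mis <- ds$train[[1]]
  mis$label <- corrupt_label(mis$label, misalignment_spec(shift = c(2, 0)))
  pair <- model_pair(arch, seed = 1)
  opt <- vesselseg:::adam_init(pair$student$params)
  wdw <- extract_window(mis$volume, 0, mis$label)
  expect_error(warmup_step(pair, list(wdw), cfg, opt), "misaligned")

  ws <- run_warmup(ds, cfg, arch)
  expect_equal(nrow(ws$log), 40)
  first <- mean(ws$log$dice_part[1:5])
  last <- mean(ws$log$dice_part[36:40])
  expect_lt(last, first)
})

test_that("the teacher replays the EMA recursion of student snapshots", {
  ds <- make_tiny_dataset(n_train = 2, seed = 5)
  cfg <- tiny_train_config(iters_warmup = 5, iters_finetune = 0, alpha = 0.9)
  arch <- tiny_arch()
  pair <- model_pair(arch, seed = 2)
  opt <- vesselseg:::adam_init(pair$student$params)
  teacher_ref <- pair$teacher$params
  set.seed(10)
  for (i in 1:5) {
    batch <- vesselseg:::sample_batch(ds$train, cfg, augmentation_policy())
    st <- warmup_step(pair, batch, cfg, opt)
    pair <- st$pair
    opt <- st$opt_state
    teacher_ref <- ema_update(teacher_ref, pair$student$params, 0.9)
  }
  expect_equal(pair$teacher$params, teacher_ref, tolerance = 1e-12)
})

test_that("fine-tune steps are bit-reproducible and honour the epsilon = 0 degenerate case", {
  ds <- make_tiny_dataset(n_train = 2, seed = 6)
  mis_spec <- misalignment_spec(shift = c(2, 0), sector = c(0, 120))
  ds$train[[2]]$label <- corrupt_label(ds$train[[2]]$label, mis_spec)
  cfg <- tiny_train_config(iters_warmup = 0, iters_finetune = 0)
  arch <- tiny_arch()
  pair <- model_pair(arch, seed = 3)
  opt <- vesselseg:::adam_init(pair$student$params)
  set.seed(20)
  batch <- vesselseg:::sample_batch(ds$train, cfg, augmentation_policy())

  a <- finetune_step(pair, batch, cfg, opt)
  b <- finetune_step(pair, batch, cfg, opt)
  expect_identical(a$dice_part, b$dice_part)
  expect_identical(a$ce_part, b$ce_part)
  expect_identical(a$pair$student$params, b$pair$student$params)

  cfg0 <- cfg
  cfg0$epsilon <- 0
  c0 <- finetune_step(pair, batch, cfg0, opt)
  expect_gt(c0$ce_part, 0)
})

test_that("two-stage training logs every iteration and returns the best checkpoint", {
  ds <- make_tiny_dataset(n_train = 2, n_val = 1, seed = 7)
  cfg <- tiny_train_config(iters_warmup = 12, iters_finetune = 12, val_every = 4)
  res <- run_two_stage(ds, cfg, tiny_arch())
  expect_equal(nrow(res$log), 24)
  expect_equal(sum(res$log$stage == "warmup"), 12)
  vals <- res$log$val_dscavg
  expect_true(any(!is.na(vals)))
  final_val <- vals[length(vals)]
  expect_gte(res$best_val, final_val)
})

test_that("the learning-rate schedule decays from the configured start", {
  cfg <- training_config(lr = 2e-4, lr_decay_start = 4000,
                         lr_decay_every = 500, lr_decay_factor = 0.9)
  expect_equal(vesselseg:::lr_schedule(1, cfg), 2e-4)
  expect_equal(vesselseg:::lr_schedule(4000, cfg), 2e-4)
  expect_equal(vesselseg:::lr_schedule(4499, cfg), 2e-4)
  expect_equal(vesselseg:::lr_schedule(4500, cfg), 2e-4 * 0.9)
  expect_equal(vesselseg:::lr_schedule(5500, cfg), 2e-4 * 0.9^3)
})
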