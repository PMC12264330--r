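#' Training configuration
#'
#' Hyperparameter defaults follow the tuned full-scale values: EMA smoothing
#' `alpha = 0.99`, manual-label weight `beta = 0.5`, hardening threshold
#' `tau = 0.99`, FGSM strength `epsilon = 4`, class weights `(2, 2, 1)`,
#' 4000 + 4000 iterations, batch size 4, Adam at learning rate `2e-4` (fixed
#' for the first 4000 iterations, then multiplied by 0.9 every 500) with
#' coupled weight decay `5e-4`. The four `ablation` switches reproduce the
#' ablation ladder: disabling `adversarial` removes Path 2 entirely
#' (baseline); `teacher_fusion` controls whether inference averages student
#' and teacher; `surrogate` controls whether misaligned volumes get surrogate
#' fitting targets (off: manual labels are used); `selective_hardening`
#' controls the hardening step inside the surrogate generator.
#'
#' @param alpha EMA coefficient in `[0, 1)`.
#' @param beta Manual-label weight in `[0, 1]`.
#' @param tau Hardening threshold.
#' @param epsilon FGSM strength (>= 0; 0 degenerates Path 2 to a second
#'   supervised branch).
#' @param weights Class weights for the weighted CE.
#' @param iters_warmup,iters_finetune Iteration counts per stage.
#' @param batch_size Windows per mini-batch.
#' @param lr,lr_decay_start,lr_decay_every,lr_decay_factor Learning-rate
#'   schedule (global iteration counter across both stages).
#' @param weight_decay Coupled Adam weight decay.
#' @param val_every Validation cadence in iterations.
#' @param seed Master seed (fans out to named substreams).
#' @param adversarial,teacher_fusion,surrogate,selective_hardening Ablation
#'   switches (all `TRUE` for the full framework).
#' @param window_mode Passed to [enumerate_windows] during validation/inference.
#' @return A `training_config` list.
#' @export
training_config <- function(alpha = 0.99, beta = 0.5, tau = 0.99, epsilon = 4,
                            weights = c(2, 2, 1),
                            iters_warmup = 4000, iters_finetune = 4000,
                            batch_size = 4, lr = 2e-4,
                            lr_decay_start = 4000, lr_decay_every = 500,
                            lr_decay_factor = 0.9, weight_decay = 5e-4,
                            val_every = 100, seed = 1L,
                            adversarial = TRUE, teacher_fusion = TRUE,
                            surrogate = TRUE, selective_hardening = TRUE,
                            window_mode = "strict") {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta <= 1, epsilon >= 0,
            iters_warmup >= 0, iters_finetune >= 0, batch_size >= 1,
            all(weights > 0))
  structure(as.list(environment()), class = "training_config")
}

lr_schedule <- function(iter, cfg) {
  if (iter <= cfg$lr_decay_start) return(cfg$lr)
  cfg$lr * cfg$lr_decay_factor^floor((iter - cfg$lr_decay_start) / cfg$lr_decay_every)
}

#' Augmentation policy
#'
#' In-plane transforms applied identically to every slice of a training
#' window (and to the label's spatial part): rotation by a multiple of 90
#' degrees, horizontal flip, then intensity-only contrast scaling and gamma
#' correction. Gamma is applied after min-max rescaling each channel to
#' `[0, 1]` (and mapping back), which keeps the transform monotone and
#' well-defined on zero-mean intensities.
#'
#' @param rotate Enable 90-degree rotations.
#' @param contrast_range,gamma_range Uniform sampling ranges.
#' @param hflip_prob Horizontal-flip probability.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotate = TRUE, contrast_range = c(0.8, 1.2),
                                gamma_range = c(0.8, 1.2), hflip_prob = 0.5) {
  structure(list(rotate = rotate, contrast_range = contrast_range,
                 gamma_range = gamma_range, hflip_prob = hflip_prob),
            class = "augmentation_policy")
}

# rotate the (H, W) plane of a (D, H, W, C) array counter-clockwise k times
rot_hw <- function(a, k) {
  k <- k %% 4
  if (k == 0) return(a)
  d <- dim(a)
  if (k == 2) return(a[, d[2]:1, d[3]:1, , drop = FALSE])
  stopifnot(d[2] == d[3])  # 90/270 need square slices
  b <- aperm(a, c(1, 3, 2, 4))
  b <- b[, dim(b)[2]:1, , , drop = FALSE]
  if (k == 1) b else rot_hw(b, 2)
}

flip_w <- function(a) a[, , dim(a)[3]:1, , drop = FALSE]

#' Sample a random 8-slice training window from a volume
#'
#' The start slice is uniform on `[0, N - 8]`; image and label are cropped
#' consistently. Draws from the current RNG state.
#'
#' @param vol An [image_volume].
#' @param label A [label_mask].
#' @return A window as returned by [extract_window].
#' @export
sample_training_window <- function(vol, label) {
  n <- dim(vol$data)[1]
  if (n < 8) stop("volume must have at least 8 slices")
  start <- sample.int(n - 8L + 1L, 1L) - 1L
  extract_window(vol, start, label)
}

#' Augment a training window
#'
#' @param window A window (list with `data`, `label`, `quality`).
#' @param policy An [augmentation_policy].
#' @return The augmented window.
#' @export
augment <- function(window, policy = augmentation_policy()) {
  x <- window$data
  y <- window$label
  if (policy$rotate) {
    k <- sample.int(4L, 1L) - 1L
    if (k %% 2 == 1 && dim(x)[2] != dim(x)[3]) {
      stop("90/270-degree rotation requires square slices")
    }
    x <- rot_hw(x, k)
    if (!is.null(y)) y <- rot_hw(y, k)
  }
  if (runif(1) < policy$hflip_prob) {
    x <- flip_w(x)
    if (!is.null(y)) y <- flip_w(y)
  }
  f <- runif(1, policy$contrast_range[1], policy$contrast_range[2])
  x <- x * f
  g <- runif(1, policy$gamma_range[1], policy$gamma_range[2])
  for (c in seq_len(dim(x)[4])) {
    ch <- x[, , , c]
    lo <- min(ch); hi <- max(ch)
    if (hi > lo) {
      x[, , , c] <- ((ch - lo) / (hi - lo))^g * (hi - lo) + lo
    }
  }
  window$data <- x
  window$label <- y
  window
}

# gradient of the multi-class Dice loss w.r.t. the logits
dice_dlogits <- function(p, y, smooth = 1e-5) {
  d <- dim(p)
  g <- array(0, dim = d)
  for (c in 1:2) {
    pc <- p[, , , c]; yc <- y[, , , c]
    num <- 2 * sum(pc * yc) + smooth
    den <- sum(pc) + sum(yc) + smooth
    g[, , , c] <- (num - 2 * yc * den) / den^2 / 2  # 1/2: mean of two classes
  }
  # back through the softmax: dz = p * (g - sum_c g_c p_c)
  pm <- matrix(p, ncol = 3)
  gm <- matrix(g, ncol = 3)
  inner <- rowSums(gm * pm)
  array(pm * (gm - inner), dim = d)
}

# gradient of the weighted CE (soft targets) w.r.t. the logits, mean over voxels
wce_dlogits <- function(p, ytilde, w) {
  d <- dim(p)
  nvox <- prod(d[1:3])
  pm <- matrix(p, ncol = 3)
  ym <- matrix(ytilde, ncol = 3)
  wy <- sweep(ym, 2, w, "*")
  array((pm * rowSums(wy) - wy) / nvox, dim = d)
}

#' One warm-up optimization step
#'
#' The student takes one Adam step on the multi-class Dice loss over a batch
#' of well-registered windows; the teacher is then updated by EMA. Misaligned
#' labels in a warm-up batch are an error.
#'
#' @param pair A [model_pair].
#' @param batch List of (augmented) windows.
#' @param cfg A [training_config].
#' @param opt_state Adam state (from an internal initializer).
#' @param lr Learning rate for this step.
#' @return List with updated `pair`, `opt_state`, and the scalar `loss`.
#' @export
warmup_step <- function(pair, batch, cfg, opt_state, lr = cfg$lr) {
  quals <- vapply(batch, function(wdw) wdw$quality, "")
  if (any(quals != "well_registered")) {
    stop("misaligned label in warm-up batch")
  }
  grads <- NULL
  loss <- 0
  for (wdw in batch) {
    fwd <- unet_forward(pair$student, wdw$data, want_cache = TRUE)
    loss <- loss + multiclass_dice_loss(fwd$probs, wdw$label)
    dlog <- dice_dlogits(fwd$probs, wdw$label)
    bwd <- unet_backward(pair$student, fwd$cache, dlog, need_dw = TRUE)
    grads <- grad_add(grads, bwd$grads)
  }
  nb <- length(batch)
  step <- adam_step(pair$student$params, grad_scale(grads, 1 / nb), opt_state,
                    lr = lr, weight_decay = cfg$weight_decay)
  pair$student$params <- step$params
  pair$teacher$params <- ema_update(pair$teacher$params, pair$student$params,
                                    cfg$alpha)
  list(pair = pair, opt_state = step$state, loss = loss / nb)
}

#' One fine-tuning optimization step
#'
#' Per window: student and teacher predict on the (augmented) image; the
#' fitting target is built (manual label for well-registered windows,
#' surrogate label for misaligned ones); an FGSM perturbation against that
#' target is added to the image; the student predicts on the perturbed image;
#' the loss is the Dice part (prediction vs manual label) plus the weighted
#' CE part (perturbed prediction vs fitting target). One Adam step on the
#' student, one EMA update of the teacher. Neither the teacher prediction nor
#' the fitting target receives gradients.
#'
#' @inheritParams warmup_step
#' @return List with `pair`, `opt_state`, `dice_part`, `ce_part`.
#' @export
finetune_step <- function(pair, batch, cfg, opt_state, lr = cfg$lr) {
  grads <- NULL
  dice_part <- 0
  ce_part <- 0
  for (wdw in batch) {
    fwd <- unet_forward(pair$student, wdw$data, want_cache = TRUE)
    dice_part <- dice_part + multiclass_dice_loss(fwd$probs, wdw$label)
    g <- unet_backward(pair$student, fwd$cache, dice_dlogits(fwd$probs, wdw$label),
                       need_dw = TRUE)$grads
    if (cfg$adversarial) {
      if (cfg$surrogate && wdw$quality == "misaligned") {
        p_tea <- unet_forward(pair$teacher, wdw$data)$probs
        p_sel <- if (cfg$selective_hardening) {
          selective_harden(p_tea, fwd$probs, cfg$tau)
        } else {
          (p_tea + fwd$probs) / 2
        }
        ytilde <- surrogate_label(wdw$label, p_sel, cfg$beta)
      } else {
        ytilde <- wdw$label
      }
      x_adv <- if (cfg$epsilon > 0) {
        r <- cfg$epsilon * sign(ce_input_gradient_cached(pair$student, fwd, ytilde))
        wdw$data + r
      } else {
        wdw$data
      }
      fwd2 <- unet_forward(pair$student, x_adv, want_cache = TRUE)
      ce_part <- ce_part + weighted_ce_loss(fwd2$probs, ytilde, cfg$weights)
      g2 <- unet_backward(pair$student, fwd2$cache,
                          wce_dlogits(fwd2$probs, ytilde, cfg$weights),
                          need_dw = TRUE)$grads
      g <- grad_add(g, g2)
    }
    grads <- grad_add(grads, g)
  }
  nb <- length(batch)
  step <- adam_step(pair$student$params, grad_scale(grads, 1 / nb), opt_state,
                    lr = lr, weight_decay = cfg$weight_decay)
  pair$student$params <- step$params
  pair$teacher$params <- ema_update(pair$teacher$params, pair$student$params,
                                    cfg$alpha)
  list(pair = pair, opt_state = step$state,
       dice_part = dice_part / nb, ce_part = ce_part / nb)
}

sample_batch <- function(recs, cfg, policy) {
  idx <- sample.int(length(recs), cfg$batch_size, replace = TRUE)
  lapply(idx, function(i) {
    wdw <- sample_training_window(recs[[i]]$volume, recs[[i]]$label)
    augment(wdw, policy)
  })
}

validation_dscavg <- function(pair, val_recs, cfg) {
  scores <- vapply(val_recs, function(rec) {
    res <- predict_volume(pair, rec$volume, fuse_teacher = cfg$teacher_fusion,
                          mode = cfg$window_mode)
    ref <- onehot_decode(rec$label)
    lum <- dsc(res$class_map == 0, ref == 0)
    outer <- dsc(res$class_map <= 1, ref <= 1)
    (lum + outer) / 2
  }, 0)
  mean(scores)
}

#' Run the warm-up stage
#'
#' Trains a fresh student/teacher pair on the well-registered training
#' volumes only, with the Dice loss. The teacher starts as a copy of the
#' student and is updated by EMA after every step.
#'
#' @param dataset List with a `train` element (list of `list(volume, label)`
#'   records); see [generate_phantom_dataset] or [load_dataset].
#' @param cfg A [training_config].
#' @param arch A [unet_config].
#' @param policy An [augmentation_policy].
#' @return A training state: `pair`, `opt_state`, `log` (data.frame), `iter`.
#' @export
run_warmup <- function(dataset, cfg, arch, policy = augmentation_policy()) {
  clean <- Filter(function(r) r$label$quality == "well_registered", dataset$train)
  if (length(clean) == 0) stop("no well-registered training volumes")
  pair <- model_pair(arch, seed = derive_seed(cfg$seed, "init"))
  opt_state <- adam_init(pair$student$params)
  log <- vector("list", cfg$iters_warmup)
  with_rng(derive_seed(cfg$seed, "warmup"), {
    for (it in seq_len(cfg$iters_warmup)) {
      batch <- sample_batch(clean, cfg, policy)
      lr <- lr_schedule(it, cfg)
      st <- warmup_step(pair, batch, cfg, opt_state, lr)
      pair <- st$pair
      opt_state <- st$opt_state
      log[[it]] <- data.frame(iter = it, stage = "warmup", lr = lr,
                              dice_part = st$loss, ce_part = NA_real_,
                              val_dscavg = NA_real_)
    }
  })
  list(pair = pair, opt_state = opt_state,
       log = do.call(rbind, log), iter = cfg$iters_warmup)
}

#' Run the fine-tuning stage
#'
#' Continues from a warm-up state on the full training set (well-registered
#' and misaligned volumes), with periodic validation; returns the checkpoint
#' with the highest validation DSCavg (mean of lumen and outer-wall DSC,
#' computed with the same fused inference used at test time).
#'
#' @param state A state from [run_warmup].
#' @param dataset List with `train` and `val` record lists.
#' @param cfg A [training_config].
#' @param policy An [augmentation_policy].
#' @return List with `pair` (best checkpoint), `final_pair`, `log`,
#'   `best_val`, `best_iter`.
#' @export
run_finetune <- function(state, dataset, cfg, policy = augmentation_policy()) {
  if (length(dataset$train) == 0) stop("empty training split")
  if (is.null(dataset$val) || length(dataset$val) == 0) stop("empty validation split")
  pair <- state$pair
  opt_state <- state$opt_state
  best_pair <- pair
  best_val <- -Inf
  best_iter <- NA_integer_
  log <- vector("list", cfg$iters_finetune)
  with_rng(derive_seed(cfg$seed, "finetune"), {
    for (it in seq_len(cfg$iters_finetune)) {
      gi <- state$iter + it
      batch <- sample_batch(dataset$train, cfg, policy)
      lr <- lr_schedule(gi, cfg)
      st <- finetune_step(pair, batch, cfg, opt_state, lr)
      pair <- st$pair
      opt_state <- st$opt_state
      val <- NA_real_
      if (it %% cfg$val_every == 0 || it == cfg$iters_finetune) {
        val <- validation_dscavg(pair, dataset$val, cfg)
        if (val >= best_val) {
          best_val <- val
          best_pair <- pair
          best_iter <- gi
        }
      }
      log[[it]] <- data.frame(iter = gi, stage = "finetune", lr = lr,
                              dice_part = st$dice_part, ce_part = st$ce_part,
                              val_dscavg = val)
    }
  })
  list(pair = best_pair, final_pair = pair, log = do.call(rbind, log),
       best_val = best_val, best_iter = best_iter)
}

#' Run the full two-stage training schedule
#'
#' Warm-up on well-registered volumes (Dice loss), then fine-tuning on the
#' complete training set (Dice + adversarial weighted CE with surrogate
#' targets), with validation-based model selection.
#'
#' @inheritParams run_warmup
#' @param dataset List with `train` and `val` record lists.
#' @return As [run_finetune], with the combined `log` of both stages.
#' @export
run_two_stage <- function(dataset, cfg, arch, policy = augmentation_policy()) {
  ws <- run_warmup(dataset, cfg, arch, policy)
  ft <- run_finetune(ws, dataset, cfg, policy)
  ft$log <- rbind(ws$log, ft$log)
  ft
}
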