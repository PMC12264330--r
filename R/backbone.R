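#' Backbone architecture configuration
#'
#' A standard 3D U-Net skeleton: per resolution level two conv(3x3x3) +
#' GroupNorm + ReLU blocks, strided-convolution downsampling, transposed-
#' convolution upsampling with skip concatenation, and a final 1x1x1
#' convolution with a 3-way softmax. Depth and width are configurable; the
#' full-scale default is depth 4 / base 16, while desk-scale experiments use
#' depth 2 / base 8 (the framework, not the backbone, is the point).
#'
#' @param depth Number of resolution levels (>= 2).
#' @param base_channels Channels at the finest level (doubled per level).
#' @param in_channels Input channels (7 contrasts).
#' @param n_classes Output classes (3).
#' @param norm_groups Max group count for group normalization; the effective
#'   count is `min(norm_groups, channels)`.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depth = 4, base_channels = 16, in_channels = 7,
                        n_classes = 3, norm_groups = 8) {
  stopifnot(depth >= 2, base_channels >= 4)
  structure(list(depth = depth, base_channels = base_channels,
                 in_channels = in_channels, n_classes = n_classes,
                 norm_groups = norm_groups),
            class = "unet_config")
}

he_init <- function(dims, fan_in) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dim = dims)
}

new_conv <- function(k, cin, cout) {
  list(w = he_init(c(k, k, k, cin, cout), k^3 * cin), b = numeric(cout))
}

new_gn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

#' Build a segmentation model
#'
#' Parameters are initialized with He-normal weights; initialization is
#' deterministic given `seed`.
#'
#' @param config A [unet_config].
#' @param seed Integer seed for weight initialization.
#' @return A `unet_model`: list with `config` and named parameter list `params`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "unet_config"))
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1)
  params <- list()
  with_rng(seed, {
    cin <- config$in_channels
    for (l in seq_len(config$depth - 1)) {
      params[[paste0("enc", l, "_conv1")]] <- new_conv(3, cin, ch[l])
      params[[paste0("enc", l, "_gn1")]] <- new_gn(ch[l])
      params[[paste0("enc", l, "_conv2")]] <- new_conv(3, ch[l], ch[l])
      params[[paste0("enc", l, "_gn2")]] <- new_gn(ch[l])
      params[[paste0("down", l)]] <- new_conv(3, ch[l], ch[l + 1])
      params[[paste0("down", l, "_gn")]] <- new_gn(ch[l + 1])
      cin <- ch[l + 1]
    }
    d <- config$depth
    params[["bottom_conv1"]] <- new_conv(3, ch[d], ch[d])
    params[["bottom_gn1"]] <- new_gn(ch[d])
    params[["bottom_conv2"]] <- new_conv(3, ch[d], ch[d])
    params[["bottom_gn2"]] <- new_gn(ch[d])
    for (l in rev(seq_len(config$depth - 1))) {
      params[[paste0("up", l)]] <- list(
        w = he_init(c(2, 2, 2, ch[l + 1], ch[l]), 8 * ch[l + 1]),
        b = numeric(ch[l]))
      params[[paste0("up", l, "_gn")]] <- new_gn(ch[l])
      params[[paste0("dec", l, "_conv1")]] <- new_conv(3, 2 * ch[l], ch[l])
      params[[paste0("dec", l, "_gn1")]] <- new_gn(ch[l])
      params[[paste0("dec", l, "_conv2")]] <- new_conv(3, ch[l], ch[l])
      params[[paste0("dec", l, "_gn2")]] <- new_gn(ch[l])
    }
    params[["head"]] <- new_conv(1, ch[1], config$n_classes)
  })
  structure(list(config = config, params = params), class = "unet_model")
}

# ---- layer primitives (R side; convolutions call the C++ kernels) ----------

gn_groups <- function(c, norm_groups) {
  g <- min(norm_groups, c)
  while (c %% g != 0) g <- g - 1
  g
}

# Channels are the trailing array dimension, so each channel (and each group
# of consecutive channels) is a contiguous block; the C++ kernels exploit
# that layout directly.
gn_fwd <- function(x, gn, groups, eps = 1e-5) {
  d <- dim(x)
  r <- .gn_fwd_cpp(x, prod(d[1:3]), d[4], groups, gn$gamma, gn$beta, eps)
  y <- r$y
  dim(y) <- d
  list(y = y,
       cache = list(xhat = r$xhat, inv_std = r$inv_std, groups = groups,
                    dims = d, gamma = gn$gamma))
}

gn_bwd <- function(dy, cache) {
  d <- cache$dims
  r <- .gn_bwd_cpp(dy, cache$xhat, cache$inv_std, cache$gamma,
                   prod(d[1:3]), d[4], cache$groups)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

relu_fwd <- function(x) {
  y <- .relu_fwd_cpp(x)
  dim(y) <- dim(x)
  y
}

conv_block_fwd <- function(x, conv, gn, groups, stride = 1, pad = 1) {
  k <- dim(conv$w)[1]
  cin <- dim(conv$w)[4]
  cout <- dim(conv$w)[5]
  z <- .conv3d_fwd(x, dim(x), conv$w, k, cin, cout, conv$b, stride, pad)
  g <- gn_fwd(z, gn, groups)
  a <- relu_fwd(g$y)
  list(y = a, cache = list(x = x, conv = conv, stride = stride, pad = pad,
                           gn_cache = g$cache, act = g$y))
}

conv_block_bwd <- function(dy, cache, need_dx = TRUE, need_dw = TRUE) {
  dy <- .relu_bwd_cpp(dy, cache$act)
  gb <- gn_bwd(dy, cache$gn_cache)
  k <- dim(cache$conv$w)[1]
  cin <- dim(cache$conv$w)[4]
  cout <- dim(cache$conv$w)[5]
  cb <- .conv3d_bwd(cache$x, dim(cache$x), cache$conv$w, k, cin, cout,
                    gb$dx, cache$stride, cache$pad, need_dx, need_dw)
  list(dx = if (need_dx) cb$dx else NULL,
       grads = list(conv = if (need_dw) list(w = cb$dw, b = cb$db) else list(b = cb$db),
                    gn = list(gamma = gb$dgamma, beta = gb$dbeta)))
}

softmax_channels <- function(z) {
  d <- dim(z)
  m <- matrix(z, ncol = d[4])
  mx <- do.call(pmax, lapply(seq_len(d[4]), function(j) m[, j]))
  e <- exp(m - mx)
  array(e / rowSums(e), dim = d)
}

#' Forward pass of the segmentation network
#'
#' @param model A `unet_model`.
#' @param x Input array `(D, H, W, in_channels)`; spatial dims must be
#'   divisible by `2^(depth - 1)`.
#' @param want_cache Keep intermediate activations for a backward pass.
#' @return List with `probs` (`(D, H, W, 3)` simplex-valued), `logits`, and
#'   `cache` (or `NULL`).
#' @export
unet_forward <- function(model, x, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  d <- dim(x)
  div <- 2^(cfg$depth - 1)
  if (any(d[1:3] %% div != 0) || any(d[1:3] / div < 1)) {
    stop("spatial dims ", paste(d[1:3], collapse = "x"),
         " not divisible by ", div)
  }
  caches <- list()
  skips <- list()
  h <- x
  for (l in seq_len(cfg$depth - 1)) {
    b1 <- conv_block_fwd(h, p[[paste0("enc", l, "_conv1")]],
                         p[[paste0("enc", l, "_gn1")]],
                         gn_groups(dim(p[[paste0("enc", l, "_conv1")]]$w)[5], cfg$norm_groups))
    b2 <- conv_block_fwd(b1$y, p[[paste0("enc", l, "_conv2")]],
                         p[[paste0("enc", l, "_gn2")]],
                         gn_groups(dim(p[[paste0("enc", l, "_conv2")]]$w)[5], cfg$norm_groups))
    skips[[l]] <- b2$y
    dn <- conv_block_fwd(b2$y, p[[paste0("down", l)]],
                         p[[paste0("down", l, "_gn")]],
                         gn_groups(dim(p[[paste0("down", l)]]$w)[5], cfg$norm_groups),
                         stride = 2)
    caches[[paste0("enc", l)]] <- list(b1 = b1$cache, b2 = b2$cache, down = dn$cache)
    h <- dn$y
  }
  b1 <- conv_block_fwd(h, p$bottom_conv1, p$bottom_gn1,
                       gn_groups(dim(p$bottom_conv1$w)[5], cfg$norm_groups))
  b2 <- conv_block_fwd(b1$y, p$bottom_conv2, p$bottom_gn2,
                       gn_groups(dim(p$bottom_conv2$w)[5], cfg$norm_groups))
  caches$bottom <- list(b1 = b1$cache, b2 = b2$cache)
  h <- b2$y
  for (l in rev(seq_len(cfg$depth - 1))) {
    up <- p[[paste0("up", l)]]
    cin <- dim(up$w)[4]
    cout <- dim(up$w)[5]
    z <- .tconv3d_fwd(h, dim(h), up$w, cin, cout, up$b)
    g <- gn_fwd(z, p[[paste0("up", l, "_gn")]], gn_groups(cout, cfg$norm_groups))
    a <- relu_fwd(g$y)
    cat_in <- abind4(a, skips[[l]])
    d1 <- conv_block_fwd(cat_in, p[[paste0("dec", l, "_conv1")]],
                         p[[paste0("dec", l, "_gn1")]],
                         gn_groups(dim(p[[paste0("dec", l, "_conv1")]]$w)[5], cfg$norm_groups))
    d2 <- conv_block_fwd(d1$y, p[[paste0("dec", l, "_conv2")]],
                         p[[paste0("dec", l, "_gn2")]],
                         gn_groups(dim(p[[paste0("dec", l, "_conv2")]]$w)[5], cfg$norm_groups))
    caches[[paste0("dec", l)]] <- list(x_up = h, gn_cache = g$cache, act = g$y,
                                       up_split = cout, b1 = d1$cache, b2 = d2$cache)
    h <- d2$y
  }
  head <- p$head
  logits <- .conv3d_fwd(h, dim(h), head$w, 1, dim(head$w)[4], dim(head$w)[5],
                        head$b, 1L, 0L)
  probs <- softmax_channels(logits)
  caches$head_in <- h
  list(probs = probs, logits = logits,
       cache = if (want_cache) caches else NULL)
}

# concatenate two (D,H,W,C) arrays along the channel axis
abind4 <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

#' Backward pass of the segmentation network
#'
#' Propagates a gradient with respect to the logits back through the network.
#'
#' @param model A `unet_model`.
#' @param cache Cache from [unet_forward] with `want_cache = TRUE`.
#' @param dlogits Gradient array w.r.t. the logits.
#' @param need_dx Return the gradient w.r.t. the input (for FGSM).
#' @param need_dw Accumulate parameter gradients.
#' @return List with `grads` (named like `params`) and `dx`.
#' @export
unet_backward <- function(model, cache, dlogits, need_dx = FALSE,
                          need_dw = TRUE) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  head <- p$head
  hb <- .conv3d_bwd(cache$head_in, dim(cache$head_in), head$w, 1,
                    dim(head$w)[4], dim(head$w)[5], dlogits, 1L, 0L,
                    TRUE, need_dw)
  if (need_dw) grads$head <- list(w = hb$dw, b = hb$db)
  dh <- hb$dx
  dskips <- list()
  for (l in seq_len(cfg$depth - 1)) {
    cc <- cache[[paste0("dec", l)]]
    b2 <- conv_block_bwd(dh, cc$b2, TRUE, need_dw)
    b1 <- conv_block_bwd(b2$dx, cc$b1, TRUE, need_dw)
    if (need_dw) {
      grads[[paste0("dec", l, "_conv2")]] <- b2$grads$conv
      grads[[paste0("dec", l, "_gn2")]] <- b2$grads$gn
      grads[[paste0("dec", l, "_conv1")]] <- b1$grads$conv
      grads[[paste0("dec", l, "_gn1")]] <- b1$grads$gn
    }
    cout <- cc$up_split
    da <- b1$dx[, , , seq_len(cout), drop = FALSE]
    dskips[[l]] <- b1$dx[, , , cout + seq_len(dim(b1$dx)[4] - cout), drop = FALSE]
    da <- .relu_bwd_cpp(da, cc$act)
    gb <- gn_bwd(da, cc$gn_cache)
    if (need_dw) grads[[paste0("up", l, "_gn")]] <- list(gamma = gb$dgamma, beta = gb$dbeta)
    up <- p[[paste0("up", l)]]
    tb <- .tconv3d_bwd(cc$x_up, dim(cc$x_up), up$w, dim(up$w)[4], dim(up$w)[5],
                       gb$dx, TRUE, need_dw)
    if (need_dw) grads[[paste0("up", l)]] <- list(w = tb$dw, b = tb$db)
    dh <- tb$dx
  }
  b2 <- conv_block_bwd(dh, cache$bottom$b2, TRUE, need_dw)
  b1 <- conv_block_bwd(b2$dx, cache$bottom$b1, TRUE, need_dw)
  if (need_dw) {
    grads$bottom_conv2 <- b2$grads$conv
    grads$bottom_gn2 <- b2$grads$gn
    grads$bottom_conv1 <- b1$grads$conv
    grads$bottom_gn1 <- b1$grads$gn
  }
  dh <- b1$dx
  dx <- NULL
  for (l in rev(seq_len(cfg$depth - 1))) {
    cc <- cache[[paste0("enc", l)]]
    dn <- conv_block_bwd(dh, cc$down, TRUE, need_dw)
    d_skip <- dn$dx + dskips[[l]]
    b2 <- conv_block_bwd(d_skip, cc$b2, TRUE, need_dw)
    last <- l == 1
    b1 <- conv_block_bwd(b2$dx, cc$b1, need_dx || !last, need_dw)
    if (need_dw) {
      grads[[paste0("down", l)]] <- dn$grads$conv
      grads[[paste0("down", l, "_gn")]] <- dn$grads$gn
      grads[[paste0("enc", l, "_conv2")]] <- b2$grads$conv
      grads[[paste0("enc", l, "_gn2")]] <- b2$grads$gn
      grads[[paste0("enc", l, "_conv1")]] <- b1$grads$conv
      grads[[paste0("enc", l, "_gn1")]] <- b1$grads$gn
    }
    if (last) dx <- b1$dx else dh <- b1$dx
  }
  list(grads = grads, dx = dx)
}

# ---- parameter-set utilities ----------------------------------------------

# Apply a binary function elementwise across two nested parameter lists.
param_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    for (fld in names(a[[nm]])) {
      out[[nm]][[fld]] <- f(a[[nm]][[fld]], b[[nm]][[fld]])
    }
  }
  out
}

#' Exponential moving average update of the teacher parameters
#'
#' `theta_t' = alpha * theta_t + (1 - alpha) * theta_s`, applied elementwise
#' to every parameter tensor (group-norm affine parameters included). The
#' teacher is never updated by gradient descent.
#'
#' @param theta_t,theta_s Teacher and student parameter lists (or plain
#'   numeric vectors/arrays of identical shape).
#' @param alpha Smoothing coefficient in `[0, 1]` (default 0.99).
#' @return The updated teacher parameters.
#' @export
ema_update <- function(theta_t, theta_s, alpha = 0.99) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (is.numeric(theta_t)) {
    stopifnot(length(theta_t) == length(theta_s))
    return(alpha * theta_t + (1 - alpha) * theta_s)
  }
  param_map2(theta_t, theta_s, function(t, s) alpha * t + (1 - alpha) * s)
}

#' Create a student/teacher model pair
#'
#' The teacher starts as an exact copy of the student and is subsequently
#' updated only by [ema_update].
#'
#' @param config A [unet_config].
#' @param seed Seed for the shared initialization.
#' @return A `model_pair` list with `student` and `teacher` `unet_model`s.
#' @export
model_pair <- function(config, seed = 1L) {
  stu <- build_model(config, seed = seed)
  structure(list(student = stu, teacher = stu, config = config),
            class = "model_pair")
}

# ---- Adam optimizer (coupled weight decay) ---------------------------------

adam_init <- function(params) {
  zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 5e-4) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (fld in names(grads[[nm]])) {
      g <- grads[[nm]][[fld]] + weight_decay * params[[nm]][[fld]]
      m <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * g
      v <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * g^2
      state$m[[nm]][[fld]] <- m
      state$v[[nm]][[fld]] <- v
      params[[nm]][[fld]] <- params[[nm]][[fld]] -
        lr * (m / bc1) / (sqrt(v / bc2) + eps)
    }
  }
  list(params = params, state = state)
}

# Sum two gradient sets (missing entries in either are kept from the other).
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  out <- a
  for (nm in names(b)) {
    if (is.null(out[[nm]])) {
      out[[nm]] <- b[[nm]]
    } else {
      for (fld in names(b[[nm]])) {
        if (is.null(out[[nm]][[fld]])) {
          out[[nm]][[fld]] <- b[[nm]][[fld]]
        } else {
          out[[nm]][[fld]] <- out[[nm]][[fld]] + b[[nm]][[fld]]
        }
      }
    }
  }
  out
}

grad_scale <- function(g, s) rapply(g, function(x) x * s, how = "replace")
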