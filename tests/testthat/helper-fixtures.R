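# Shared fixtures and independent oracles used across the test files.

# A small phantom configuration for fast tests.
tiny_phantom_config <- function(seed = 1L, H = 32, W = 32, noise_sd = 1,
                                texture_sd = 0.3) {
  small <- min(H, W) < 24
  phantom_config(N = 8, H = H, W = W,
                 lumen_radius = if (small) 3 else 4,
                 wall_radius = if (small) 5 else 7,
                 centerline_amplitude = if (small) 1 else 2,
                 noise_sd = noise_sd,
                 noise_cor = 0.3, texture_sd = texture_sd, seed = seed)
}

tiny_arch <- function() unet_config(depth = 2, base_channels = 4)

# Random voxel-wise simplex map of shape (N, H, W, 3).
random_simplex <- function(d3, concentrated = FALSE) {
  n <- prod(d3)
  m <- matrix(rexp(n * 3), ncol = 3)
  if (concentrated) {
    # push some voxels toward high confidence
    idx <- sample.int(n, n %/% 2)
    m[cbind(idx, sample.int(3, length(idx), TRUE))] <- rexp(length(idx)) + 50
  }
  array(m / rowSums(m), dim = c(d3, 3))
}

# Independent brute-force re-implementation of selective hardening for a
# single voxel pair of probability vectors.
harden_voxel_oracle <- function(pt, ps, tau) {
  u <- which(pt == max(pt))
  v <- which(ps == max(ps))
  if (length(u) == 1 && length(v) == 1 && u == v && pt[u] > tau && ps[v] > tau) {
    out <- c(0, 0, 0)
    out[u] <- 1
    out
  } else {
    (pt + ps) / 2
  }
}

# Exhaustive all-pairs surface-distance oracle (boundary via in-plane
# 4-connectivity, distances in 3D physical coordinates).
surface_distance_oracle <- function(pred, ref, spacing) {
  boundary <- function(mask) {
    d <- dim(mask)
    out <- NULL
    for (s in seq_len(d[1])) for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
      if (!mask[s, h, w]) next
      nb <- c(
        if (h > 1) mask[s, h - 1, w] else FALSE,
        if (h < d[2]) mask[s, h + 1, w] else FALSE,
        if (w > 1) mask[s, h, w - 1] else FALSE,
        if (w < d[3]) mask[s, h, w + 1] else FALSE)
      if (!all(nb)) out <- rbind(out, c(s, h, w))
    }
    out
  }
  ba <- boundary(pred)
  bb <- boundary(ref)
  pa <- sweep(ba, 2, spacing, "*")
  pb <- sweep(bb, 2, spacing, "*")
  mins_a <- apply(pa, 1, function(p) min(sqrt(colSums((t(pb) - p)^2))))
  mins_b <- apply(pb, 1, function(p) min(sqrt(colSums((t(pa) - p)^2))))
  pool <- c(mins_a, mins_b)
  c(hd95 = unname(quantile(pool, 0.95)), asd = mean(pool))
}

# Simple permutation test on the difference of group means (two-sided).
permutation_pvalue <- function(a, b, n_perm = 2000) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_perm + 1)
}

# Scalar reference cross-entropy for one-hot targets (independent of the
# package implementation).
scalar_ce_onehot <- function(p_mat, true_class) {
  mean(-log(p_mat[cbind(seq_len(nrow(p_mat)), true_class)]))
}
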