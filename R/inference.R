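#' Fused student/teacher inference over slice windows
#'
#' Each 8-slice window is predicted by the student (and, with
#' `fuse_teacher = TRUE`, the teacher, averaging the two probability maps);
#' slices covered by two windows receive the mean of their two window
#' probabilities. Each voxel is assigned the class with the largest averaged
#' probability; argmax ties resolve to the lowest channel index
#' (lumen before wall before background).
#'
#' @param pair A [model_pair].
#' @param vol An [image_volume] with at least 8 slices.
#' @param fuse_teacher Average student and teacher probabilities.
#' @param mode Window enumeration mode (see [enumerate_windows]).
#' @return A `segmentation_result`: list with `class_map` (integer array,
#'   0 = lumen, 1 = wall, 2 = background), `fused_probs`, `volume_id`.
#' @export
predict_volume <- function(pair, vol, fuse_teacher = TRUE, mode = "strict") {
  starts <- enumerate_windows(vol, mode = mode)
  d <- dim(vol$data)
  acc <- array(0, dim = c(d[1:3], 3))
  cnt <- numeric(d[1])
  for (s in starts) {
    wdw <- extract_window(vol, s)
    p <- unet_forward(pair$student, wdw$data)$probs
    if (fuse_teacher) {
      p <- (p + unet_forward(pair$teacher, wdw$data)$probs) / 2
    }
    idx <- seq.int(s + 1, s + 8)
    acc[idx, , , ] <- acc[idx, , , ] + p
    cnt[idx] <- cnt[idx] + 1
  }
  for (s in seq_len(d[1])) acc[s, , , ] <- acc[s, , , ] / cnt[s]
  m <- matrix(acc, ncol = 3)
  cm <- array(max.col(m, ties.method = "first") - 1L, dim = d[1:3])
  structure(list(class_map = cm, fused_probs = acc, volume_id = vol$id),
            class = "segmentation_result")
}

#' Dice similarity coefficient in percent
#'
#' `100 * 2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly (100);
#' one empty mask scores 0.
#'
#' @param pred_mask,ref_mask Logical (or 0/1) arrays of identical shape.
#' @return A scalar in `[0, 100]`.
#' @export
dsc <- function(pred_mask, ref_mask) {
  check_same_shape(pred_mask, ref_mask)
  a <- sum(pred_mask)
  b <- sum(ref_mask)
  if (a + b == 0) return(100)
  100 * 2 * sum(pred_mask & ref_mask) / (a + b)
}

# Boundary voxels: foreground with at least one face-adjacent non-foreground
# neighbour in-plane (4-connectivity per slice; out-of-image counts as
# non-foreground). Returns an (n x 3) index matrix (slice, row, col).
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, dim = d + c(0, 2, 2))
  pad[, 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  core <- pad[, 2:(d[2] + 1), 2:(d[3] + 1), drop = FALSE]
  nb <- pad[, 1:d[2], 2:(d[3] + 1), drop = FALSE] &
    pad[, 3:(d[2] + 2), 2:(d[3] + 1), drop = FALSE] &
    pad[, 2:(d[2] + 1), 1:d[3], drop = FALSE] &
    pad[, 2:(d[2] + 1), 3:(d[3] + 2), drop = FALSE]
  which(core & !nb, arr.ind = TRUE)
}

directed_min_dists <- function(a, b) {
  # rows of a, b: physical coordinates; returns min distance from each a-row
  # to b.  Squared distances use explicit coordinate differences (the
  # expanded a^2 + b^2 - 2ab form loses precision to cancellation).
  out <- numeric(nrow(a))
  chunk <- max(1L, floor(2e6 / nrow(b)))
  for (i0 in seq(1, nrow(a), by = chunk)) {
    idx <- i0:min(i0 + chunk - 1, nrow(a))
    d2 <- outer(a[idx, 1], b[, 1], "-")^2 +
      outer(a[idx, 2], b[, 2], "-")^2 +
      outer(a[idx, 3], b[, 3], "-")^2
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' Surface distances between two segmentation boundaries
#'
#' Boundary voxels are extracted per slice with in-plane 4-connectivity;
#' distances are Euclidean in 3D physical coordinates (anisotropic spacing).
#' HD95 is the 95th percentile of the pooled symmetric directed-distance set;
#' ASD is its mean.
#'
#' @param pred_mask,ref_mask Nonempty logical arrays `(N, H, W)`.
#' @param spacing Voxel spacing `(slice, row, col)` in mm.
#' @return Named numeric vector `c(hd95, asd)` in mm, or `c(NA, NA)` with a
#'   warning if either mask is empty.
#' @export
surface_distances <- function(pred_mask, ref_mask, spacing = c(1, 1, 1)) {
  check_same_shape(pred_mask, ref_mask)
  if (sum(pred_mask) == 0 || sum(ref_mask) == 0) {
    warning("empty mask: surface distances undefined")
    return(c(hd95 = NA_real_, asd = NA_real_))
  }
  ba <- boundary_voxels(pred_mask)
  bb <- boundary_voxels(ref_mask)
  pa <- sweep(ba, 2, spacing, "*")
  pb <- sweep(bb, 2, spacing, "*")
  pool <- c(directed_min_dists(pa, pb), directed_min_dists(pb, pa))
  c(hd95 = unname(quantile(pool, 0.95)), asd = mean(pool))
}

#' Evaluate a predicted segmentation against a reference
#'
#' Computes DSC for the vessel wall (class 1), lumen (class 0) and outer
#' wall (the union of lumen and wall — the region enclosed by the outer
#' boundary), HD95/ASD for lumen and outer wall, and DSCavg (mean of lumen
#' and outer-wall DSC).
#'
#' @param result A `segmentation_result` (or integer class map).
#' @param ref A [label_mask] (or integer class map).
#' @param spacing Voxel spacing in mm.
#' @return A one-row data.frame of metrics.
#' @export
evaluate_volume <- function(result, ref, spacing = c(1, 1, 1)) {
  pred <- if (inherits(result, "segmentation_result")) result$class_map else result
  refm <- if (inherits(ref, "label_mask")) onehot_decode(ref) else ref
  check_same_shape(pred, refm)
  vid <- if (inherits(result, "segmentation_result")) result$volume_id else NA_character_
  dsc_lumen <- dsc(pred == 0, refm == 0)
  dsc_wall <- dsc(pred == 1, refm == 1)
  dsc_outer <- dsc(pred <= 1, refm <= 1)
  sd_lumen <- suppressWarnings(surface_distances(pred == 0, refm == 0, spacing))
  sd_outer <- suppressWarnings(surface_distances(pred <= 1, refm <= 1, spacing))
  data.frame(volume_id = vid,
             dsc_wall = dsc_wall, dsc_lumen = dsc_lumen, dsc_outer = dsc_outer,
             hd95_lumen = sd_lumen[["hd95"]], asd_lumen = sd_lumen[["asd"]],
             hd95_outer = sd_outer[["hd95"]], asd_outer = sd_outer[["asd"]],
             dsc_avg = (dsc_lumen + dsc_outer) / 2,
             stringsAsFactors = FALSE)
}

#' All-pairs comparison of per-volume scores across methods
#'
#' Tukey's honestly-significant-difference test on a one-way layout
#' (family-wise error controlled at 0.05 via the studentized range).
#'
#' @param scores Named list of numeric vectors, one per method (each with at
#'   least 2 observations).
#' @return A data.frame with one row per method pair: `pair`, `diff`,
#'   `lwr`, `upr`, `p_adj`.
#' @export
compare_methods <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 2, !is.null(names(scores)))
  ns <- lengths(scores)
  if (any(ns < 2)) {
    stop("each method needs at least 2 observations: ",
         paste(names(scores)[ns < 2], collapse = ", "))
  }
  df <- data.frame(
    value = unlist(scores, use.names = FALSE),
    method = factor(rep(names(scores), ns), levels = names(scores)))
  tk <- TukeyHSD(aov(value ~ method, data = df))$method
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}
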