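#' Selectively harden ensembled student/teacher predictions
#'
#' Per voxel: if the teacher and student agree on the argmax class and both
#' assign it probability strictly greater than `tau`, the voxel is snapped to
#' the one-hot vector of that class; otherwise the voxel keeps the
#' elementwise mean of the two predictions. Ties in the argmax (two channels
#' sharing the maximum) count as disagreement. `tau = 1` therefore disables
#' hardening entirely, and `tau = 1/3` hardens every agreeing voxel.
#'
#' @param p_tea,p_stu Probability arrays `(N, H, W, 3)` (teacher, student).
#' @param tau Confidence threshold in `[1/3, 1]`.
#' @return A probability array of the same shape (the hardened pseudo-label).
#' @export
selective_harden <- function(p_tea, p_stu, tau = 0.99) {
  check_same_shape(p_tea, p_stu)
  d <- dim(p_tea)
  mt <- matrix(p_tea, ncol = 3)
  ms <- matrix(p_stu, ncol = 3)
  u <- max.col(mt, ties.method = "first")
  v <- max.col(ms, ties.method = "first")
  u_last <- max.col(mt, ties.method = "last")
  v_last <- max.col(ms, ties.method = "last")
  pt_max <- mt[cbind(seq_len(nrow(mt)), u)]
  ps_max <- ms[cbind(seq_len(nrow(ms)), v)]
  harden <- (u == v) & (u == u_last) & (v == v_last) &
    (pt_max > tau) & (ps_max > tau)
  out <- (mt + ms) / 2
  if (any(harden)) {
    out[harden, ] <- 0
    out[cbind(which(harden), u[harden])] <- 1
  }
  array(out, dim = d)
}

#' Surrogate label: convex combination of manual label and pseudo-label
#'
#' `beta * y + (1 - beta) * p_sel`. With `beta = 1` the manual label is kept
#' unchanged; with `beta = 0` the pseudo-label replaces it entirely.
#'
#' @param y Manual label ([label_mask] or one-hot array).
#' @param p_sel Hardened pseudo-label array.
#' @param beta Manual-label weight in `[0, 1]`.
#' @return A probability array (the surrogate label).
#' @export
surrogate_label <- function(y, p_sel, beta = 0.5) {
  stopifnot(beta >= 0, beta <= 1)
  y <- as_prob_array(y)
  check_same_shape(y, p_sel)
  beta * y + (1 - beta) * p_sel
}

#' Fitting target for the adversarial path
#'
#' Well-registered volumes are fitted to their manual label unchanged.
#' Misaligned volumes are fitted to the surrogate label built from the
#' selectively hardened student/teacher ensemble. The returned target is
#' treated as a constant during optimization (no gradient flows into it).
#'
#' @param y A [label_mask] carrying a quality flag.
#' @param p_tea,p_stu Current teacher and student probability maps.
#' @param tau Hardening threshold.
#' @param beta Manual-label weight.
#' @param selective With `FALSE`, hardening is skipped and the pseudo-label
#'   is the plain student/teacher mean (the ablation without selective
#'   hardening).
#' @return A probability array.
#' @export
fitting_target <- function(y, p_tea, p_stu, tau = 0.99, beta = 0.5,
                           selective = TRUE) {
  stopifnot(inherits(y, "label_mask"))
  if (is.null(y$quality)) stop("label is missing its quality flag")
  if (y$quality == "well_registered") {
    return(y$onehot)
  }
  p_sel <- if (selective) {
    selective_harden(p_tea, p_stu, tau)
  } else {
    (p_tea + p_stu) / 2
  }
  surrogate_label(y, p_sel, beta)
}
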