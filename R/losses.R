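#' Binary (soft) Dice loss
#'
#' `1 - 2 * sum(x * xhat) / (sum(x) + sum(xhat))`, computed jointly over all
#' voxels of the (3D) input. A small smoothing term `s` is added to numerator
#' and denominator so that the empty-vs-empty case is defined as loss 0.
#'
#' @param x,xhat Non-negative arrays of identical shape (typically a binary
#'   reference mask and a probability map).
#' @param smooth Smoothing constant (default `1e-5`).
#' @return A scalar in `[0, 1]` for inputs in `[0, 1]`.
#' @export
binary_dice_loss <- function(x, xhat, smooth = 1e-5) {
  if (!identical(dim(x), dim(xhat)) && length(x) != length(xhat)) {
    stop("shape mismatch in binary_dice_loss")
  }
  1 - (2 * sum(x * xhat) + smooth) / (sum(x) + sum(xhat) + smooth)
}

#' Multi-class Dice loss over the lumen and vessel-wall channels
#'
#' The mean of the binary Dice losses for the lumen channel and the
#' vessel-wall channel; the background channel is excluded. Computed
#' volumetrically (all voxels of the window jointly), not per-slice.
#'
#' @param p Probability array `(N, H, W, 3)`.
#' @param y One-hot reference: a [label_mask] or `(N, H, W, 3)` array.
#' @return A scalar loss in `[0, 1]`.
#' @export
multiclass_dice_loss <- function(p, y) {
  y <- as_prob_array(y)
  check_same_shape(p, y)
  (binary_dice_loss(y[, , , 1], p[, , , 1]) +
     binary_dice_loss(y[, , , 2], p[, , , 2])) / 2
}

#' Weighted cross-entropy loss with soft targets
#'
#' Mean over voxels of `sum_j -w[j] * ytilde[j] * log(p[j])`. Targets may be
#' soft (the surrogate-label case); a one-hot target is the special case.
#' Probabilities are clamped to `[1e-7, 1]` inside the logarithm.
#'
#' @param p_adv Predicted probability array `(N, H, W, 3)`.
#' @param ytilde Target array `(N, H, W, 3)` with entries in `[0, 1]`.
#' @param w Length-3 class weights, default `c(2, 2, 1)` for
#'   (lumen, wall, background).
#' @return A non-negative scalar.
#' @export
weighted_ce_loss <- function(p_adv, ytilde, w = c(2, 2, 1)) {
  ytilde <- as_prob_array(ytilde)
  check_same_shape(p_adv, ytilde)
  stopifnot(length(w) == 3, all(w > 0))
  nvox <- prod(dim(p_adv)[1:3])
  lp <- log(pmin(pmax(p_adv, 1e-7), 1))
  total <- 0
  for (j in 1:3) total <- total - w[j] * sum(ytilde[, , , j] * lp[, , , j])
  total / nvox
}

#' Joint fine-tuning loss: Dice (clean path) + weighted CE (adversarial path)
#'
#' The student is supervised by the multi-class Dice loss against the manual
#' label on the unperturbed input, plus the weighted cross-entropy between
#' its prediction on the adversarially perturbed input and the fitting
#' target (manual label for well-registered volumes, surrogate label for
#' misaligned ones).
#'
#' @param p_stu Student probabilities on the unperturbed input.
#' @param y Manual one-hot label.
#' @param p_adv Student probabilities on the perturbed input.
#' @param ytilde Fitting target for the adversarial path.
#' @param w Class weights for the CE term.
#' @return A scalar loss.
#' @export
total_finetune_loss <- function(p_stu, y, p_adv, ytilde, w = c(2, 2, 1)) {
  multiclass_dice_loss(p_stu, y) + weighted_ce_loss(p_adv, ytilde, w)
}

# Accept a label_mask or a plain probability array.
as_prob_array <- function(y) {
  if (inherits(y, "label_mask")) y$onehot else y
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
  }
  invisible(TRUE)
}
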