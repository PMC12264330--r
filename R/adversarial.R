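#' Gradient of the (unweighted) cross-entropy with respect to the input image
#'
#' Generic used by [fgsm_perturbation]: implementations must return the
#' gradient of the voxel-mean unweighted cross-entropy `D(p(i), ytilde)`
#' with respect to `image`, leaving the model parameters untouched. The
#' unweighted form is deliberately distinct from the weighted CE used as the
#' training loss.
#'
#' @param model A segmentation model.
#' @param image Input array.
#' @param ytilde Fitting-target probability array.
#' @return Gradient array with the shape of `image`.
#' @export
ce_input_gradient <- function(model, image, ytilde) {
  UseMethod("ce_input_gradient")
}

#' @export
ce_input_gradient.unet_model <- function(model, image, ytilde) {
  fwd <- unet_forward(model, image, want_cache = TRUE)
  nvox <- prod(dim(image)[1:3])
  # d(mean CE)/dlogits for softmax + CE with simplex-valued soft targets
  dlogits <- (fwd$probs - ytilde) / nvox
  unet_backward(model, fwd$cache, dlogits, need_dx = TRUE, need_dw = FALSE)$dx
}

# Reuse an existing forward cache (same image, same parameters) to avoid a
# redundant forward pass during fine-tuning.
ce_input_gradient_cached <- function(model, fwd, ytilde) {
  nvox <- prod(dim(fwd$probs)[1:3])
  dlogits <- (fwd$probs - ytilde) / nvox
  unet_backward(model, fwd$cache, dlogits, need_dx = TRUE, need_dw = FALSE)$dx
}

#' Fast gradient sign method (FGSM) perturbation
#'
#' `r_adv = epsilon * sign(grad_i D(p(i), ytilde))` where `D` is the
#' unweighted voxel-mean cross-entropy. Every entry of the result is in
#' `{-epsilon, 0, +epsilon}` (`sign(0) = 0`), and the model parameters are
#' unchanged. `epsilon` is interpreted in the standard-deviation units of the
#' normalized image; the default follows the tuned value of 4.
#'
#' @param model A model with a [ce_input_gradient] method.
#' @param image Input array (or [image_volume]).
#' @param ytilde Fitting-target probability array.
#' @param epsilon Perturbation strength (> 0).
#' @return Perturbation array with the shape of the image.
#' @export
fgsm_perturbation <- function(model, image, ytilde, epsilon = 4) {
  stopifnot(epsilon > 0)
  x <- if (inherits(image, "image_volume")) image$data else image
  g <- ce_input_gradient(model, x, ytilde)
  epsilon * sign(g)
}

#' Apply a perturbation to an image
#'
#' Elementwise addition; the perturbed image is deliberately not clipped or
#' re-normalized (intensities live in normalized units).
#'
#' @param image An [image_volume] or array.
#' @param r Perturbation array of matching shape.
#' @return Same type as `image`.
#' @export
perturb_image <- function(image, r) {
  if (inherits(image, "image_volume")) {
    check_same_shape(image$data, r)
    image$data <- image$data + r
    return(image)
  }
  check_same_shape(image, r)
  image + r
}

#' A one-voxel linear-softmax toy segmenter
#'
#' Maps a length-`n` input to 3 class probabilities via `softmax(W x + b)`.
#' Used as a transparent test bed for adversarial-perturbation properties.
#'
#' @param W 3 x n weight matrix.
#' @param b Length-3 bias.
#' @return A `linear_softmax_model`.
#' @export
linear_softmax_model <- function(W, b = numeric(3)) {
  stopifnot(nrow(W) == 3)
  structure(list(W = W, b = b), class = "linear_softmax_model")
}

#' @export
ce_input_gradient.linear_softmax_model <- function(model, image, ytilde) {
  x <- as.numeric(image)
  z <- as.numeric(model$W %*% x + model$b)
  p <- exp(z - max(z))
  p <- p / sum(p)
  g <- as.numeric(t(model$W) %*% (p - as.numeric(ytilde)))
  if (is.array(image)) array(g, dim = dim(image)) else g
}
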