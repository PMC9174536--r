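# Training objective: weighted cross-entropy (per-image background weight)
# plus a small Dice term for the heavy vessel/background imbalance.

#' Default loss parameters
#'
#' `alpha_ce = 0.2` scales the positive (vessel) cross-entropy term,
#' `beta = 0.01` weights the Dice term, `eps` clips probabilities before
#' logs, `dice_eps` (one pixel-unit) guards the Dice ratio against 0/0.
#'
#' @param alpha_ce,beta,eps,dice_eps Overrides of the defaults.
#' @return A named list.
#' @export
loss_params <- function(alpha_ce = 0.2, beta = 0.01, eps = 1e-7, dice_eps = 1.0) {
  if (alpha_ce <= 0) stop("alpha_ce must be positive")
  if (beta < 0) stop("beta must be non-negative")
  list(alpha_ce = alpha_ce, beta = beta, eps = eps, dice_eps = dice_eps)
}

#' Background class weight of a mask
#'
#' `w = 1 - sum(y) / (H * W)`: the background fraction of one image's mask,
#' used to down-weight the abundant background class in the cross-entropy.
#'
#' @param y Binary mask (matrix or vector).
#' @return A single number in \[0, 1\].
#' @export
class_weight <- function(y) {
  if (length(y) == 0L) stop("empty mask raster")
  1 - sum(y) / length(y)
}

check_same_shape <- function(y, p) {
  if (length(y) != length(p)) {
    stop("mask and prediction shapes differ: ", length(y), " vs ", length(p), " pixels")
  }
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of
#' `-(alpha_ce * w * y * log(p) + (1 - w) * (1 - y) * log(1 - p))`, with the
#' background weight `w` from [class_weight()] computed on this image and
#' probabilities clipped to `[eps, 1 - eps]`.
#'
#' @param y Binary mask.
#' @param p Prediction in \[0, 1\], same shape.
#' @param params See [loss_params()].
#' @return Non-negative scalar loss.
#' @export
weighted_ce <- function(y, p, params = loss_params()) {
  check_same_shape(y, p)
  w <- class_weight(y)
  pc <- pmin(pmax(p, params$eps), 1 - params$eps)
  mean(-(params$alpha_ce * w * y * log(pc) + (1 - w) * (1 - y) * log(1 - pc)))
}

#' Dice loss
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`: one minus the
#' (soft) Dice overlap between prediction and mask.
#'
#' @inheritParams weighted_ce
#' @return Scalar in \[0, 1\] (up to the eps guard).
#' @export
dice_loss <- function(y, p, params = loss_params()) {
  check_same_shape(y, p)
  1 - (2 * sum(y * p) + params$dice_eps) / (sum(y) + sum(p) + params$dice_eps)
}

#' Combined training loss
#'
#' `weighted_ce + beta * dice_loss`.
#'
#' @inheritParams weighted_ce
#' @return Scalar loss.
#' @export
total_loss <- function(y, p, params = loss_params()) {
  weighted_ce(y, p, params) + params$beta * dice_loss(y, p, params)
}

# Gradient of total_loss w.r.t. p for one image (vectors).  Zero where the
# probability was clipped.
total_loss_grad <- function(y, p, params = loss_params()) {
  n <- length(y)
  w <- class_weight(y)
  pc <- pmin(pmax(p, params$eps), 1 - params$eps)
  inside <- (p > params$eps) & (p < 1 - params$eps)
  dce <- (-params$alpha_ce * w * y / pc + (1 - w) * (1 - y) / (1 - pc)) / n
  sy <- sum(y); sp <- sum(p)
  denom <- sy + sp + params$dice_eps
  num <- 2 * sum(y * p) + params$dice_eps
  ddice <- -(2 * y * denom - num) / denom^2
  dce * inside + params$beta * ddice
}
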