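#' Smoothed (soft) Dice loss
#'
#' Dice loss between a predicted probability map and a binary target,
#' \deqn{L = 1 - \frac{2\sum p\,t + s}{\sum p + \sum t + s},}
#' where the additive (Laplace) smoothing constant `s` keeps the ratio
#' defined when both maps are empty and stabilises gradients on sparse
#' targets. The soft product sum generalises the set intersection
#' \eqn{|X \cap Y|} to probabilities; on hard masks with `smoothing = 0` the
#' loss equals one minus the Dice coefficient `2TP / (2TP + FP + FN)`.
#'
#' @param predicted Numeric array in [0, 1].
#' @param target Binary array of the same shape.
#' @param smoothing Non-negative additive smoothing constant (default 1).
#' @return Scalar loss in [0, 1].
#' @examples
#' a <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(a, a, smoothing = 0)                 # 0: perfect overlap
#' dice_loss(a, 1 - a, smoothing = 0)             # 1: disjoint
#' @export
dice_loss <- function(predicted, target, smoothing = 1) {
  if (!all(dim(predicted) == dim(target)) ||
      length(predicted) != length(target)) {
    stop("`predicted` and `target` must have identical shapes", call. = FALSE)
  }
  stopifnot(smoothing >= 0)
  s_pt <- sum(predicted * target)
  s_p <- sum(predicted)
  s_t <- sum(target)
  denom <- s_p + s_t + smoothing
  if (denom == 0) return(0)   # both empty, no smoothing: define loss as 0
  1 - (2 * s_pt + smoothing) / denom
}

# Gradient of dice_loss with respect to `predicted` (same shape).
dice_loss_grad <- function(predicted, target, smoothing = 1) {
  s_pt <- sum(predicted * target)
  s_p <- sum(predicted)
  s_t <- sum(target)
  denom <- s_p + s_t + smoothing
  -(2 * target * denom - (2 * s_pt + smoothing)) / denom^2
}

#' Hard Dice accuracy between two binary masks
#'
#' The Dice coefficient \eqn{2|X \cap Y| / (|X| + |Y|)}; the complement of
#' [dice_loss()] at zero smoothing on hard masks. Two empty masks agree that
#' there is no target, so that case is defined as 1.
#'
#' @param predicted,truth Binary arrays of identical shape.
#' @return Scalar in [0, 1].
#' @examples
#' m <- matrix(c(1, 1, 1, 0), 2)
#' dice_accuracy(m, m)
#' @export
dice_accuracy <- function(predicted, truth) {
  if (!all(dim(predicted) == dim(truth)) ||
      length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have identical shapes", call. = FALSE)
  }
  p <- predicted > 0.5
  t <- truth > 0.5
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}
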