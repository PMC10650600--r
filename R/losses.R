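# Joint segmentation loss: mean binary cross-entropy plus smoothed Dice loss.

#' Binary cross-entropy loss
#'
#' Mean over all pixels of `-(y*log p + (1-y)*log(1-p))`.  Predictions are
#' clipped to `[eps_clip, 1 - eps_clip]` for log-safety.
#'
#' @param y true labels in \{0,1\} (any shape).
#' @param p predicted probabilities in `[0,1]`, same length as `y`.
#' @param eps_clip clipping bound for the probabilities.
#' @return non-negative scalar.
#' @export
bce_loss <- function(y, p, eps_clip = 1e-7) {
  if (length(y) != length(p)) stop_fmt("y and p must have equal length")
  p <- pmin(pmax(p, eps_clip), 1 - eps_clip)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Dice loss
#'
#' `1 - (2*sum(y*p) + eps) / (sum(y) + sum(p) + eps)`, a smoothed complement
#' of the Dice overlap coefficient; robust to the vessel/background class
#' imbalance.  The smoothing constant defaults to 1e-5.
#'
#' @inheritParams bce_loss
#' @param epsilon smoothing constant, must be positive.
#' @return value in `[0, 1]`.
#' @export
dice_loss <- function(y, p, epsilon = 1e-5) {
  if (length(y) != length(p)) stop_fmt("y and p must have equal length")
  if (epsilon <= 0) stop_fmt("epsilon must be > 0")
  1 - (2 * sum(y * p) + epsilon) / (sum(y) + sum(p) + epsilon)
}

#' Joint loss: BCE + Dice
#' @inheritParams dice_loss
#' @param eps_clip clipping bound used inside the BCE term.
#' @return scalar loss.
#' @export
joint_loss <- function(y, p, epsilon = 1e-5, eps_clip = 1e-7) {
  bce_loss(y, p, eps_clip) + dice_loss(y, p, epsilon)
}

# gradient of the joint loss w.r.t. p (same shape as p)
joint_loss_grad <- function(y, p, epsilon = 1e-5, eps_clip = 1e-7) {
  pc <- pmin(pmax(p, eps_clip), 1 - eps_clip)
  g_bce <- (-y / pc + (1 - y) / (1 - pc)) / length(y)
  num <- 2 * sum(y * p) + epsilon
  den <- sum(y) + sum(p) + epsilon
  g_dice <- -(2 * y * den - num) / den^2
  g <- g_bce + g_dice
  dim(g) <- dim(p)
  g
}
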