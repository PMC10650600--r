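# Strip attention: a horizontal attention mechanism (one W x W matrix over
# image columns) and a vertical attention mechanism (one H x H matrix over
# image rows), each built from 1x1 conv + BN + ReLU projections, fused
# residually with the input through learnable scalars lambda1, lambda2 that
# start at zero, so a freshly initialised module is the identity.

#' Create strip-attention parameters
#'
#' Builds the parameter set of a strip attention module for feature maps with
#' `channels` channels: three 1x1 conv + batch-norm + ReLU projection stacks
#' per mechanism (producing query/key/value), one 1x1 conv + BN + ReLU output
#' stack per mechanism, and the residual fusion scalars `lambda1`, `lambda2`
#' (initialised to 0, so the module starts as the identity map).
#'
#' @param channels number of feature-map channels C (projections preserve C).
#' @param softmax `"as_printed"` normalises each attention matrix over its
#'   first index (columns sum to 1); `"over_keys"` uses the conventional
#'   normalisation over the second index.
#' @param seed optional integer seed for the He-style weight initialisation.
#' @return an object of class `strip_attention_params`.
#' @export
new_strip_attention_params <- function(channels,
                                       softmax = c("as_printed", "over_keys"),
                                       seed = NULL) {
  softmax <- match.arg(softmax)
  if (!is.null(seed)) set.seed(seed)
  p <- list(
    q_h = nn_cbr(channels, channels, 1L), k_h = nn_cbr(channels, channels, 1L),
    v_h = nn_cbr(channels, channels, 1L),
    q_v = nn_cbr(channels, channels, 1L), k_v = nn_cbr(channels, channels, 1L),
    v_v = nn_cbr(channels, channels, 1L),
    out_h = nn_cbr(channels, channels, 1L), out_v = nn_cbr(channels, channels, 1L),
    lambda = nn_lambda(),
    channels = as.integer(channels),
    softmax = softmax
  )
  class(p) <- "strip_attention_params"
  p
}

# internal: [C,H,W] user-facing feature map -> [H,W,C,1] engine tensor
chw_to_hwcb <- function(X) {
  if (length(dim(X)) != 3L) stop_fmt("expected a [C,H,W] array")
  if (any(!is.finite(X))) stop_fmt("feature map contains non-finite values")
  d <- dim(X)
  array(aperm(X, c(2L, 3L, 1L)), dim = c(d[2], d[3], d[1], 1L))
}

hwcb_to_chw <- function(x) {
  d <- dim(x)
  aperm(array(x, dim = d[1:3]), c(3L, 1L, 2L))
}

# one attention mechanism in inference mode, exposed for testing
axis_attention_infer <- function(X, params, axis) {
  x <- as_node(chw_to_hwcb(X))
  pq <- if (axis == "w") params$q_h else params$q_v
  pk <- if (axis == "w") params$k_h else params$k_v
  pv <- if (axis == "w") params$v_h else params$v_v
  q <- cbr_fwd(pq, x, NULL, FALSE)
  k <- cbr_fwd(pk, x, NULL, FALSE)
  v <- cbr_fwd(pv, x, NULL, FALSE)
  z <- op_axis_attention(NULL, q, k, v, axis, params$softmax)
  list(Z = hwcb_to_chw(z$v), A = attr(z, "attention")[[1L]],
       Q = hwcb_to_chw(q$v), K = hwcb_to_chw(k$v), V = hwcb_to_chw(v$v))
}

#' Horizontal attention mechanism (inference mode)
#'
#' Projects the input through the query/key/value 1x1 conv + BN + ReLU stacks,
#' reshapes queries and keys to `[W, C*H]`, forms the `W x W` horizontal
#' attention matrix by softmax over the similarity matrix, and mixes the value
#' columns with it. Batch norm uses the stored running statistics.
#'
#' @param X feature map, array `[C, H, W]`.
#' @param params a [new_strip_attention_params()] object.
#' @return list with `Z1` (`[C,H,W]` output) and `AW` (`W x W` attention
#'   matrix; with the default softmax each column sums to 1).
#' @export
horizontal_attention <- function(X, params) {
  r <- axis_attention_infer(X, params, "w")
  list(Z1 = r$Z, AW = r$A)
}

#' Vertical attention mechanism (inference mode)
#'
#' Mirror of [horizontal_attention()] over the row axis: queries and keys are
#' reshaped to `[H, C*W]` and an `H x H` attention matrix mixes the value rows.
#'
#' @inheritParams horizontal_attention
#' @return list with `Z2` (`[C,H,W]`) and `AH` (`H x H` attention matrix).
#' @export
vertical_attention <- function(X, params) {
  r <- axis_attention_infer(X, params, "h")
  list(Z2 = r$Z, AH = r$A)
}

#' Full strip-attention module forward pass (inference mode)
#'
#' Computes `Z = X + lambda1 * O1 + lambda2 * O2`, where `O1`/`O2` are the
#' horizontal/vertical attention outputs each passed through a 1x1 conv + BN +
#' ReLU stack. With freshly initialised parameters (`lambda1 = lambda2 = 0`)
#' the output equals the input exactly.
#'
#' @inheritParams horizontal_attention
#' @return feature map `[C, H, W]`.
#' @export
strip_attention_forward <- function(X, params) {
  x <- as_node(chw_to_hwcb(X))
  z <- strip_module_fwd(params, x, NULL, FALSE)
  hwcb_to_chw(z$v)
}

# engine-level forward used inside the network (records on the tape)
strip_module_fwd <- function(params, x, tape, training) {
  q1 <- cbr_fwd(params$q_h, x, tape, training)
  k1 <- cbr_fwd(params$k_h, x, tape, training)
  v1 <- cbr_fwd(params$v_h, x, tape, training)
  z1 <- op_axis_attention(tape, q1, k1, v1, "w", params$softmax)
  o1 <- cbr_fwd(params$out_h, z1, tape, training)
  q2 <- cbr_fwd(params$q_v, x, tape, training)
  k2 <- cbr_fwd(params$k_v, x, tape, training)
  v2 <- cbr_fwd(params$v_v, x, tape, training)
  z2 <- op_axis_attention(tape, q2, k2, v2, "h", params$softmax)
  o2 <- cbr_fwd(params$out_v, z2, tape, training)
  op_lambda_add(tape, x, o1, o2, params$lambda)
}

#' Dense self-attention reference (explicit loops)
#'
#' Literal evaluation of dense self-attention over all `N = H*W` positions:
#' the `N x N` similarity matrix is normalised position-by-position with the
#' same softmax convention as the strip mechanisms, and the values are mixed
#' with its transpose. Quadratic in `N`; used only as a test reference for the
#' strip mechanisms, never inside the network.
#'
#' @param Q,K,V matrices `[C, N]`.
#' @param softmax `"as_printed"` (normalise over the first index) or
#'   `"over_keys"`.
#' @return list with `Z` (`[C, N]`) and `A` (`[N, N]`).
#' @export
dense_self_attention_oracle <- function(Q, K, V,
                                        softmax = c("as_printed", "over_keys")) {
  softmax <- match.arg(softmax)
  if (!all(dim(Q) == dim(K)) || !all(dim(Q) == dim(V)))
    stop_fmt("Q, K, V must share the same [C, N] shape")
  N <- ncol(Q)
  S <- matrix(0, N, N)
  for (i in seq_len(N))
    for (j in seq_len(N))
      S[i, j] <- sum(Q[, i] * K[, j])
  A <- matrix(0, N, N)
  if (softmax == "as_printed") {
    for (j in seq_len(N)) {
      e <- exp(S[, j] - max(S[, j]))
      A[, j] <- e / sum(e)
    }
  } else {
    for (i in seq_len(N)) {
      e <- exp(S[i, ] - max(S[i, ]))
      A[i, ] <- e / sum(e)
    }
  }
  Z <- matrix(0, nrow(V), N)
  for (cc in seq_len(nrow(V)))
    for (i in seq_len(N))
      Z[cc, i] <- sum(V[cc, ] * A[i, ])
  list(Z = Z, A = A)
}
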