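# Independent reference implementations used as oracles.  They are written
# with explicit loops, deliberately sharing no code with the package.

# horizontal/vertical attention arithmetic on already-projected Q, K, V
# ([C,H,W] arrays); softmax normalised over the first index.
brute_axis_attention <- function(Q, K, V, axis) {
  d <- dim(Q); C <- d[1]; H <- d[2]; W <- d[3]
  n <- if (axis == "w") W else H
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    s <- 0
    if (axis == "w") {
      for (cc in seq_len(C)) for (h in seq_len(H))
        s <- s + Q[cc, h, i] * K[cc, h, j]
    } else {
      for (cc in seq_len(C)) for (w in seq_len(W))
        s <- s + Q[cc, i, w] * K[cc, j, w]
    }
    S[i, j] <- s
  }
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- exp(S[, j] - max(S[, j]))
    A[, j] <- e / sum(e)
  }
  Z <- array(0, dim = d)
  for (cc in seq_len(C)) for (h in seq_len(H)) for (w in seq_len(W)) {
    s <- 0
    if (axis == "w") {
      for (j in seq_len(n)) s <- s + V[cc, h, j] * A[w, j]
    } else {
      for (j in seq_len(n)) s <- s + V[cc, j, w] * A[h, j]
    }
    Z[cc, h, w] <- s
  }
  list(Z = Z, A = A)
}

# AUC as the Mann-Whitney pair statistic (ties count 1/2), exhaustive
pair_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# set every strip-attention lambda in a module tree to given values
set_lambdas <- function(x, l1, l2) {
  walk <- function(m) {
    if (inherits(m, "nn_lambda")) { m$l1 <- l1; m$l2 <- l2 }
    else if (is.list(m) && !inherits(m, "nn_layer")) for (el in m) walk(el)
  }
  walk(unclass(x))
  invisible(x)
}

# randomise BN running statistics so inference mode is non-trivial
randomize_bn_stats <- function(x, seed = 1) {
  set.seed(seed)
  walk <- function(m) {
    if (inherits(m, "nn_bn")) {
      m$run_mean <- stats::runif(m$ch, -0.3, 0.3)
      m$run_var <- stats::runif(m$ch, 0.5, 1.5)
    } else if (is.list(m) && !inherits(m, "nn_layer")) for (el in m) walk(el)
  }
  walk(unclass(x))
  invisible(x)
}

small_phantom_cfg <- function(seed = 1L, ...) {
  synthetic_config(height = 96L, width = 96L, n_trees = 2L, width_min = 1,
                   width_max = 8, seed = seed, ...)
}
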