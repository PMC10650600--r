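test_that("dense self-attention reference handles the degenerate cases", {
  # single position: softmax of a scalar is 1, output is V
  r1 <- dense_self_attention_oracle(matrix(1, 2, 1), matrix(2, 2, 1),
                                    matrix(c(3, 4), 2, 1))
  expect_equal(r1$A, matrix(1, 1, 1))
  expect_equal(r1$Z, matrix(c(3, 4), 2, 1))
  # zero queries/keys: uniform attention, mean-pooled values broadcast
  V <- matrix(rnorm(12), 2, 6)
  r2 <- dense_self_attention_oracle(matrix(0, 2, 6), matrix(0, 2, 6), V)
  expect_true(all(abs(r2$A - 1 / 6) < 1e-12))
  expect_equal(r2$Z, matrix(rowMeans(V), 2, 6, byrow = FALSE) * 1,
               tolerance = 1e-12)
  expect_error(dense_self_attention_oracle(matrix(0, 2, 3), matrix(0, 2, 4),
                                           matrix(0, 2, 4)), "shape")
})

test_that("dense reference matches an independent matrix-algebra coding", {
  set.seed(1)
  Q <- matrix(rnorm(12), 2, 6); K <- matrix(rnorm(12), 2, 6)
  V <- matrix(rnorm(12), 2, 6)
  r <- dense_self_attention_oracle(Q, K, V)
  S <- t(Q) %*% K
  E <- exp(sweep(S, 2, apply(S, 2, max)))
  A <- sweep(E, 2, colSums(E), "/")
  Z <- V %*% t(A)
  expect_lt(max(abs(r$A - A)), 1e-6)
  expect_lt(max(abs(r$Z - Z)), 1e-6)
})

test_that("strip mechanisms collapse correctly on single rows/columns", {
  pa <- new_strip_attention_params(2L, seed = 3L)
  randomize_bn_stats(pa, 4)
  X <- array(rnorm(2 * 5 * 1), c(2, 5, 1))     # W = 1
  h <- horizontal_attention(X, pa)
  expect_equal(h$AW, matrix(1, 1, 1))
  pr <- stripseg:::axis_attention_infer(X, pa, "w")
  expect_equal(h$Z1, pr$V)                     # Z1 is the projected V itself
  Xv <- array(rnorm(2 * 1 * 5), c(2, 1, 5))    # H = 1
  v <- vertical_attention(Xv, pa)
  expect_equal(v$AH, matrix(1, 1, 1))
})

test_that("identical spatial columns give uniform horizontal attention", {
  pa <- new_strip_attention_params(3L, seed = 5L)
  randomize_bn_stats(pa, 6)
  col <- matrix(rnorm(3 * 4), 3, 4)
  X <- array(0, dim = c(3, 4, 6))
  for (w in 1:6) X[, , w] <- col
  h <- horizontal_attention(X, pa)
  expect_true(all(abs(h$AW - 1 / 6) < 1e-9))
})

test_that("strip mechanisms match the brute-force loop oracle", {
  for (seed in 1:4) {
    pa <- new_strip_attention_params(2L, seed = seed)
    randomize_bn_stats(pa, seed + 10)
    X <- array(rnorm(2 * 3 * 4), c(2, 3, 4))
    pr_w <- stripseg:::axis_attention_infer(X, pa, "w")
    bw <- brute_axis_attention(pr_w$Q, pr_w$K, pr_w$V, "w")
    expect_lt(max(abs(pr_w$Z - bw$Z)), 1e-5)
    expect_lt(max(abs(pr_w$A - bw$A)), 1e-5)
    X2 <- array(rnorm(2 * 4 * 3), c(2, 4, 3))
    pr_h <- stripseg:::axis_attention_infer(X2, pa, "h")
    bh <- brute_axis_attention(pr_h$Q, pr_h$K, pr_h$V, "h")
    expect_lt(max(abs(pr_h$Z - bh$Z)), 1e-5)
    expect_lt(max(abs(pr_h$A - bh$A)), 1e-5)
  }
})

test_that("vertical attention is the spatial transpose of horizontal", {
  pa <- new_strip_attention_params(2L, seed = 8L)
  randomize_bn_stats(pa, 9)
  # params with the horizontal and vertical projection stacks swapped
  pb <- pa
  pb$q_h <- pa$q_v; pb$k_h <- pa$k_v; pb$v_h <- pa$v_v
  pb$q_v <- pa$q_h; pb$k_v <- pa$k_h; pb$v_v <- pa$v_h
  X <- array(rnorm(2 * 4 * 5), c(2, 4, 5))
  v <- vertical_attention(X, pa)
  Xt <- aperm(X, c(1, 3, 2))
  h <- horizontal_attention(Xt, pb)
  expect_lt(max(abs(v$Z2 - aperm(h$Z1, c(1, 3, 2)))), 1e-9)
  expect_lt(max(abs(v$AH - h$AW)), 1e-9)
})

test_that("attention matrices are column-stochastic and compact", {
  pa <- new_strip_attention_params(3L, seed = 12L)
  randomize_bn_stats(pa, 13)
  X <- array(rnorm(3 * 7 * 9), c(3, 7, 9))
  h <- horizontal_attention(X, pa)
  v <- vertical_attention(X, pa)
  expect_true(all(abs(colSums(h$AW) - 1) < 1e-6))
  expect_true(all(abs(colSums(v$AH) - 1) < 1e-6))
  expect_true(all(h$AW >= 0) && all(v$AH >= 0))
  # one W x W plus one H x H matrix: H^2 + W^2 entries, < (H*W)^2 dense
  n_strip <- length(h$AW) + length(v$AH)
  expect_equal(n_strip, 9^2 + 7^2)
  expect_lt(n_strip, (7 * 9)^2)
})

test_that("row permutations act equivariantly on horizontal attention", {
  pa <- new_strip_attention_params(2L, seed = 14L)
  randomize_bn_stats(pa, 15)
  X <- array(rnorm(2 * 5 * 6), c(2, 5, 6))
  perm <- c(3, 1, 5, 2, 4)
  h0 <- horizontal_attention(X, pa)
  hp <- horizontal_attention(X[, perm, , drop = FALSE], pa)
  expect_lt(max(abs(hp$AW - h0$AW)), 1e-9)
  expect_lt(max(abs(hp$Z1 - h0$Z1[, perm, , drop = FALSE])), 1e-9)
  # dually: column permutations for the vertical mechanism
  v0 <- vertical_attention(X, pa)
  cperm <- c(6, 2, 4, 1, 5, 3)
  vp <- vertical_attention(X[, , cperm, drop = FALSE], pa)
  expect_lt(max(abs(vp$AH - v0$AH)), 1e-9)
  expect_lt(max(abs(vp$Z2 - v0$Z2[, , cperm, drop = FALSE])), 1e-9)
})

test_that("the residual module is the identity at initialisation", {
  pa <- new_strip_attention_params(4L, seed = 21L)
  X <- array(rnorm(4 * 6 * 8), c(4, 6, 8))
  expect_identical(strip_attention_forward(X, pa), X)   # bit-for-bit
})

test_that("the residual composition follows its fusion equation", {
  pa <- new_strip_attention_params(2L, seed = 22L)
  randomize_bn_stats(pa, 23)
  X <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  eng <- asNamespace("stripseg")
  branch <- function(axis, out_stack) {
    z <- eng$axis_attention_infer(X, pa, axis)$Z
    zn <- eng$as_node(eng$chw_to_hwcb(z))
    eng$hwcb_to_chw(eng$cbr_fwd(out_stack, zn, NULL, FALSE)$v)
  }
  o1 <- branch("w", pa$out_h)
  o2 <- branch("h", pa$out_v)
  # lambda1 = 1, lambda2 = 0: difference from X is exactly the horizontal branch
  pa$lambda$l1 <- 1; pa$lambda$l2 <- 0
  expect_lt(max(abs(strip_attention_forward(X, pa) - X - o1)), 1e-9)
  # generic lambdas: full composition
  pa$lambda$l1 <- 0.6; pa$lambda$l2 <- -0.3
  Z <- strip_attention_forward(X, pa)
  expect_lt(max(abs(Z - (X + 0.6 * o1 - 0.3 * o2))), 1e-6)
})

test_that("non-finite inputs are rejected", {
  pa <- new_strip_attention_params(2L, seed = 1L)
  X <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
  X[1] <- NaN
  expect_error(horizontal_attention(X, pa), "finite")
})

test_that("the over-keys softmax option gives row-stochastic matrices", {
  pa <- new_strip_attention_params(2L, softmax = "over_keys", seed = 31L)
  randomize_bn_stats(pa, 32)
  X <- array(rnorm(2 * 4 * 6), c(2, 4, 6))
  h <- horizontal_attention(X, pa)
  expect_true(all(abs(rowSums(h$AW) - 1) < 1e-6))
})
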