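test_that("the three streams carry C/2C/4C channels at 1, 1/2, 1/4 resolution", {
  cfg <- network_config(base_channels = 16L, n_fusion_stages = 3L, seed = 1L)
  net <- build_network(cfg)
  expect_equal(net$stem$conv$out_ch, 16L)
  expect_equal(net$transitions$medium$conv$in_ch, 16L)
  expect_equal(net$transitions$medium$conv$out_ch, 32L)
  expect_equal(net$transitions$medium$conv$stride, 2L)
  expect_equal(net$transitions$low$conv$in_ch, 32L)
  expect_equal(net$transitions$low$conv$out_ch, 64L)
  expect_equal(stripseg:::stream_hw(48L, "high"), 48L)
  expect_equal(stripseg:::stream_hw(48L, "medium"), 24L)
  expect_equal(stripseg:::stream_hw(48L, "low"), 12L)
  expect_error(network_config(base_channels = 0), "base_channels")
  expect_error(network_config(attention_streams = "top"), "subset")
})

test_that("forward output is a probability map of the input size", {
  net <- build_network(network_config(base_channels = 4L, seed = 2L))
  init_weights(net, 2)
  x <- array(runif(24 * 32 * 1 * 2), c(24, 32, 1, 2))
  p <- net_forward(net, x)
  expect_equal(dim(p), c(24L, 32L, 1L, 2L))
  expect_true(all(p > 0 & p < 1))
  p0 <- net_forward(net, array(0, dim = c(24, 24, 1, 1)))
  expect_true(all(is.finite(p0)))
  expect_error(net_forward(net, array(0, dim = c(22, 24, 1, 1))), "divisible by 4")
  expect_error(net_forward(net, array(0, dim = c(24, 24, 2, 1))), "channel")
})

test_that("builds are deterministic per seed", {
  cfg <- network_config(base_channels = 4L, seed = 9L)
  w1 <- get_weights(build_network(cfg))
  w2 <- get_weights(build_network(cfg))
  expect_identical(w1, w2)
  cfg2 <- network_config(base_channels = 4L, seed = 10L)
  expect_false(identical(w1, get_weights(build_network(cfg2))))
})

test_that("at initialisation the attention network equals its baseline", {
  cfg <- network_config(base_channels = 4L, seed = 3L)
  net <- build_network(cfg)
  init_weights(net, 3)
  # strip the attention modules while sharing every remaining layer
  base <- net
  base$fusions <- lapply(net$fusions, function(fu) { fu$att <- list(); fu })
  base$head$att <- NULL
  x <- array(runif(24 * 24 * 1 * 2), c(24, 24, 1, 2))
  expect_identical(net_forward(net, x), net_forward(base, x))
  # and strictly more parameters with attention present
  cfgb <- cfg; cfgb$attention_enabled <- FALSE
  expect_gt(count_parameters(net), count_parameters(build_network(cfgb)))
})

test_that("parameter counts scale quadratically in the width", {
  n1 <- count_parameters(build_network(network_config(base_channels = 4L, seed = 1L)))
  n2 <- count_parameters(build_network(network_config(base_channels = 8L, seed = 1L)))
  expect_gt(n2 / n1, 3.4)
  expect_lt(n2 / n1, 4.1)
  # stable across rebuilds
  expect_equal(n1, count_parameters(build_network(network_config(base_channels = 4L, seed = 7L))))
})

test_that("receptive field follows the stacked-kernel formula", {
  expect_equal(receptive_field(c(3, 3)), 5)    # two 3x3 see a 5x5 window
  expect_equal(receptive_field(3), 3)
  expect_equal(receptive_field(c(3, 3, 3)), 7)
  expect_error(receptive_field(integer(0)), "non-empty")
  expect_error(receptive_field(c(3, 4)), "odd")
})

test_that("an impulse probe reproduces the analytic receptive field", {
  eng <- asNamespace("stripseg")
  set.seed(11)
  x <- array(0, dim = c(15, 15, 1, 1))
  x[8, 8, 1, 1] <- 1
  y <- x
  for (i in 1:3) {
    W <- matrix(rnorm(9), 9, 1)
    y <- eng$conv2d_fwd_cpp(y, W, 0, 15L, 15L, 1L, 1L, 3L, 3L, 1L, 1L, FALSE)
  }
  nz <- which(abs(y[, , 1, 1]) > 1e-12, arr.ind = TRUE)
  extent <- max(nz[, 1]) - min(nz[, 1]) + 1
  expect_equal(extent, receptive_field(c(3, 3, 3)))
})

test_that("every parameter receives gradient within a few steps", {
  eng <- asNamespace("stripseg")
  net <- build_network(network_config(base_channels = 2L, convs_per_stage = 1L,
                                      seed = 4L))
  init_weights(net, 4)
  refs <- eng$collect_param_refs(unclass(net))
  opt <- eng$adam_init(refs)
  seen <- lapply(refs, function(r) r$env[[r$field]] * 0)
  set.seed(5)
  for (s in 1:5) {
    x <- array(runif(16 * 16 * 1 * 4), c(16, 16, 1, 4))
    y <- array(rbinom(16 * 16 * 4, 1, 0.3), c(16, 16, 1, 4))
    tape <- eng$new_tape()
    out <- eng$net_forward_node(net, x, tape = tape, training = TRUE)
    eng$zero_grads(refs)
    eng$backward(tape, out, eng$joint_loss_grad(y, out$v))
    for (i in seq_along(refs))
      seen[[i]] <- seen[[i]] + abs(refs[[i]]$env[[refs[[i]]$gfield]])
    opt <- eng$adam_step(refs, opt, 1e-3, 1e-4)
  }
  touched <- vapply(seen, function(s) all(s > 0), logical(1))
  expect_true(all(touched))
})

test_that("analytic gradients agree with finite differences", {
  eng <- asNamespace("stripseg")
  net <- build_network(network_config(base_channels = 2L, convs_per_stage = 1L,
                                      seed = 6L))
  init_weights(net, 6)
  set_lambdas(net, 0.5, -0.4)     # activate the attention branches
  set.seed(7)
  x <- array(runif(8 * 8 * 1 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2))
  refs <- eng$collect_param_refs(unclass(net))
  tape <- eng$new_tape()
  out <- eng$net_forward_node(net, x, tape = tape, training = TRUE)
  eng$zero_grads(refs)
  eng$backward(tape, out, eng$joint_loss_grad(y, out$v))
  lossfn <- function() joint_loss(y, eng$net_forward_node(net, x, NULL, TRUE)$v)
  set.seed(8)
  for (t in 1:10) {
    r <- refs[[sample(length(refs), 1)]]
    pv <- r$env[[r$field]]
    ii <- sample(length(pv), 1)
    e <- 1e-4
    r$env[[r$field]][ii] <- pv[ii] + e; lp <- lossfn()
    r$env[[r$field]][ii] <- pv[ii] - e; lm <- lossfn()
    r$env[[r$field]][ii] <- pv[ii]
    fd <- (lp - lm) / (2 * e)
    an <- r$env[[r$gfield]][ii]
    # convolution arithmetic runs in single precision: tolerance reflects it
    expect_lt(abs(fd - an), 5e-3 + 0.05 * (abs(fd) + abs(an)))
  }
})

test_that("checkpoints rebuild the exact same network", {
  net <- build_network(network_config(base_channels = 2L, seed = 13L))
  init_weights(net, 13)
  x <- array(runif(16 * 16 * 1 * 2), c(16, 16, 1, 2))
  invisible(net_forward(net, x, training = TRUE))  # move BN running stats
  ck <- tempfile(fileext = ".rds")
  save_checkpoint(net, ck)
  net2 <- load_checkpoint(ck)
  expect_identical(get_weights(net), get_weights(net2))
  expect_identical(net_forward(net, x), net_forward(net2, x))
  expect_true(file.exists(paste0(ck, ".json")))
})
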