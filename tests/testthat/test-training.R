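test_that("He initialisation has the right scale and leaves lambdas at zero", {
  net <- build_network(network_config(base_channels = 16L, seed = 1L))
  set_lambdas(net, 0.5, 0.5)
  init_weights(net, 42)
  lam_ok <- TRUE
  std_ok <- TRUE
  walk <- function(m) {
    if (inherits(m, "nn_lambda")) {
      if (m$l1 != 0 || m$l2 != 0) lam_ok <<- FALSE
    } else if (inherits(m, "nn_conv")) {
      if (length(m$W) >= 1000) {
        target <- sqrt(2 / nrow(m$W))
        if (abs(stats::sd(m$W) - target) / target > 0.1) std_ok <<- FALSE
      }
    } else if (is.list(m) && !inherits(m, "nn_layer")) for (el in m) walk(el)
  }
  walk(unclass(net))
  expect_true(lam_ok)
  expect_true(std_ok)
  w1 <- get_weights(init_weights(build_network(network_config(base_channels = 4L, seed = 1L)), 9))
  w2 <- get_weights(init_weights(build_network(network_config(base_channels = 4L, seed = 2L)), 9))
  expect_identical(w1, w2)   # init seed, not build seed, fixes the weights
})

test_that("the plateau schedule halves after exactly 5 flat epochs", {
  cfg <- train_config(seed = 1)
  st <- schedule_init(cfg)
  for (l in c(1.0, 0.9, 0.9, 0.9, 0.9, 0.9)) st <- schedule_step(st, l)
  expect_equal(st$lr, 1e-3)                     # only 4 non-improving so far
  st <- schedule_step(st, 0.9)                  # 5th non-improving epoch
  expect_equal(st$lr, 5e-4)
  expect_false(st$stop)
})

test_that("strictly decreasing losses never drop the LR nor stop", {
  st <- schedule_init(train_config(seed = 1))
  for (l in seq(1, 0.1, by = -0.05)) st <- schedule_step(st, l)
  expect_equal(st$lr, 1e-3)
  expect_false(st$stop)
  expect_equal(st$best_epoch, st$epoch)
})

test_that("early stopping fires exactly stop_patience epochs after the best", {
  cfg <- train_config(seed = 1)
  st <- schedule_init(cfg)
  st <- schedule_step(st, 1.0)
  st <- schedule_step(st, 0.5)                  # best at epoch 2
  for (i in 1:19) {
    st <- schedule_step(st, 0.5)
    expect_false(st$stop)
  }
  st <- schedule_step(st, 0.5)                  # 20th non-improving
  expect_true(st$stop)
  expect_equal(st$epoch - st$best_epoch, cfg$stop_patience)
  # LR has been halved on the way down (after epochs 7, 12, 17, 22)
  expect_equal(st$lr, 1e-3 * 0.5^4)
})

test_that("training is reproducible and selects the best epoch", {
  set.seed(20)
  img <- matrix(runif(64 * 64), 64)
  lab <- matrix(0, 64, 64); lab[20:40, 20:40] <- 1
  ps <- sample_random_patches(img, lab, 48, size = 16L, seed = 3L)
  sp <- split_validation(ps, 0.25, seed = 3L)
  cfg <- train_config(batch_size = 12L, max_epochs = 3L, seed = 5L)
  run <- function() {
    net <- build_network(network_config(base_channels = 2L, convs_per_stage = 1L,
                                        seed = 5L))
    init_weights(net, 5)
    list(net = net, res = train_network(net, sp$train, sp$val, cfg))
  }
  a <- run(); b <- run()
  expect_equal(a$res$log, b$res$log)
  expect_identical(get_weights(a$net), get_weights(b$net))
  # returned weights reproduce the logged minimum validation loss
  expect_equal(a$res$best_val_loss, min(a$res$log$val_loss), tolerance = 1e-12)
  reval <- stripseg:::eval_loss(a$net, sp$val, cfg$batch_size)
  expect_equal(reval, a$res$best_val_loss, tolerance = 1e-9)
  expect_error(train_network(a$net, sp$train,
                             stripseg:::patch_subset(sp$val, integer(0), "val"),
                             cfg), "empty")
})

test_that("the learning-rate column is non-increasing with factor-0.5 drops", {
  st <- schedule_init(train_config(seed = 1))
  lrs <- numeric(0)
  set.seed(2)
  losses <- cumsum(rnorm(40, 0, 0.02)) + 1    # wandering, mostly flat
  for (l in losses) {
    if (st$stop) break
    lrs <- c(lrs, st$lr)
    st <- schedule_step(st, l)
  }
  expect_true(all(diff(lrs) <= 0))
  r <- unique(lrs[-1] / utils::head(lrs, -1))
  expect_true(all(r %in% c(1, 0.5)))
})
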