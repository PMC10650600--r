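# Optimisation protocol: He initialisation, minibatch Adam on the joint
# BCE+Dice loss, validation after every epoch, plateau learning-rate halving
# (5 non-improving epochs), early stopping (20), and selection of the
# minimum-validation-loss weights.

#' Training configuration
#'
#' Defaults follow the published protocol: batch 64, Adam with initial
#' learning rate 1e-3 and weight decay 1e-4, learning rate halved after 5
#' consecutive non-improving validation epochs, training stopped after 20.
#'
#' @param batch_size minibatch size.
#' @param lr_init initial learning rate.
#' @param weight_decay L2 penalty added to the gradient.
#' @param plateau_patience non-improving epochs before the LR is halved.
#' @param stop_patience non-improving epochs before training stops.
#' @param lr_factor multiplicative LR drop (0.5 = halving).
#' @param seed integer seed for shuffling.
#' @param max_epochs safety bound on the number of epochs.
#' @param improve_tol minimum decrease of the validation loss that counts as
#'   an improvement.
#' @return object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, lr_init = 1e-3, weight_decay = 1e-4,
                         plateau_patience = 5L, stop_patience = 20L,
                         lr_factor = 0.5, seed = 1L, max_epochs = 150L,
                         improve_tol = 1e-6) {
  if (plateau_patience >= stop_patience)
    stop_fmt("plateau_patience must be < stop_patience")
  if (lr_factor <= 0 || lr_factor >= 1) stop_fmt("lr_factor must be in (0,1)")
  if (batch_size < 1L) stop_fmt("batch_size must be >= 1")
  cfg <- list(batch_size = as.integer(batch_size), lr_init = lr_init,
              weight_decay = weight_decay,
              plateau_patience = as.integer(plateau_patience),
              stop_patience = as.integer(stop_patience),
              lr_factor = lr_factor, seed = as.integer(seed),
              max_epochs = as.integer(max_epochs), improve_tol = improve_tol)
  class(cfg) <- "train_config"
  cfg
}

#' He-style weight initialisation
#'
#' Re-initialises every conv weight from N(0, 2/fan_in) (fan-in, ReLU gain),
#' zeroes biases, resets batch-norm to scale 1 / shift 0 with fresh running
#' statistics, and leaves the attention fusion scalars at 0.  Deterministic
#' per seed.
#'
#' @param net a built network (modified in place).
#' @param seed integer seed.
#' @return the network, invisibly.
#' @export
init_weights <- function(net, seed = 1L) {
  stopifnot(inherits(net, "hr_network"))   # forces `net` before reseeding
  set.seed(seed)
  walk <- function(m) {
    if (inherits(m, "nn_conv")) {
      fan_in <- nrow(m$W)
      m$W <- matrix(stats::rnorm(length(m$W), sd = sqrt(2 / fan_in)),
                    nrow(m$W), ncol(m$W))
      m$b <- numeric(length(m$b))
    } else if (inherits(m, "nn_bn")) {
      m$gamma <- rep(1, m$ch); m$beta <- rep(0, m$ch)
      m$run_mean <- rep(0, m$ch); m$run_var <- rep(1, m$ch)
    } else if (inherits(m, "nn_lambda")) {
      m$l1 <- 0; m$l2 <- 0
    } else if (is.list(m)) for (el in m) walk(el)
  }
  walk(unclass(net))
  invisible(net)
}

#' Initialise the LR schedule / early-stopping state
#' @param cfg a [train_config()].
#' @return schedule state list.
#' @export
schedule_init <- function(cfg) {
  list(lr = cfg$lr_init, best = Inf, best_epoch = 0L, epoch = 0L,
       plateau = 0L, since_best = 0L, stop = FALSE, cfg = cfg)
}

#' Advance the LR schedule by one epoch
#'
#' An epoch improves when its validation loss is below the best-so-far by
#' more than `improve_tol`.  After `plateau_patience` consecutive
#' non-improving epochs the learning rate is multiplied by `lr_factor` and
#' the plateau counter restarts; after `stop_patience` consecutive
#' non-improving epochs the stop flag is set.
#'
#' @param state schedule state from [schedule_init()].
#' @param epoch_val_loss validation loss of the finished epoch.
#' @return updated state.
#' @export
schedule_step <- function(state, epoch_val_loss) {
  cfg <- state$cfg
  state$epoch <- state$epoch + 1L
  if (epoch_val_loss < state$best - cfg$improve_tol) {
    state$best <- epoch_val_loss
    state$best_epoch <- state$epoch
    state$plateau <- 0L
    state$since_best <- 0L
  } else {
    state$plateau <- state$plateau + 1L
    state$since_best <- state$since_best + 1L
    if (state$plateau >= cfg$plateau_patience) {
      state$lr <- state$lr * cfg$lr_factor
      state$plateau <- 0L
    }
    if (state$since_best >= cfg$stop_patience) state$stop <- TRUE
  }
  state
}

adam_init <- function(refs) {
  list(t = 0L, m = lapply(refs, function(r) r$env[[r$field]] * 0),
       v = lapply(refs, function(r) r$env[[r$field]] * 0))
}

adam_step <- function(refs, st, lr, wd, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (i in seq_along(refs)) {
    r <- refs[[i]]
    g <- r$env[[r$gfield]]
    if (is.null(g)) g <- r$env[[r$field]] * 0
    g <- g + wd * r$env[[r$field]]
    st$m[[i]] <- beta1 * st$m[[i]] + (1 - beta1) * g
    st$v[[i]] <- beta2 * st$v[[i]] + (1 - beta2) * g * g
    r$env[[r$field]] <- r$env[[r$field]] -
      lr * (st$m[[i]] / bc1) / (sqrt(st$v[[i]] / bc2) + eps)
  }
  st
}

patch_batch <- function(ps, idx) {
  s <- dim(ps$images)[1]
  x <- ps$images[, , idx, drop = FALSE]
  y <- ps$labels[, , idx, drop = FALSE]
  dim(x) <- c(s, s, 1L, length(idx))
  dim(y) <- c(s, s, 1L, length(idx))
  list(x = x, y = y)
}

eval_loss <- function(net, ps, batch_size) {
  n <- n_patches(ps)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    b <- patch_batch(ps, idx)
    p <- net_forward(net, b$x, training = FALSE)
    tot <- tot + joint_loss(b$y, p) * length(idx)
  }
  tot / n
}

#' Train the network
#'
#' Minibatch Adam on the joint BCE+Dice loss with per-epoch reshuffling,
#' validation loss after every epoch driving [schedule_step()], and selection
#' of the weights of the minimum-validation-loss epoch.  Fully reproducible
#' for a fixed seed on one machine.
#'
#' @param net a built network (modified in place; the returned best weights
#'   are also restored into it).
#' @param train_set,val_set `patch_set` objects (non-empty).
#' @param cfg a [train_config()].
#' @param verbose print per-epoch progress.
#' @return object of class `train_result`: `log` (per-epoch data frame with
#'   train loss, validation loss and learning rate), `best_epoch`,
#'   `best_val_loss`, `best_weights`.
#' @export
train_network <- function(net, train_set, val_set, cfg = train_config(),
                          verbose = FALSE) {
  if (n_patches(train_set) == 0L || n_patches(val_set) == 0L)
    stop_fmt("empty patch set")
  refs <- collect_param_refs(unclass(net))
  opt <- adam_init(refs)
  sched <- schedule_init(cfg)
  n <- n_patches(train_set)
  log <- data.frame(epoch = integer(), train_loss = numeric(),
                    val_loss = numeric(), lr = numeric())
  best_w <- NULL; best_bn <- NULL
  for (epoch in seq_len(cfg$max_epochs)) {
    set.seed(cfg$seed + 7919L * epoch)
    ord <- sample.int(n)
    tot <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      b <- patch_batch(train_set, idx)
      tape <- new_tape()
      out <- net_forward_node(net, b$x, tape = tape, training = TRUE)
      loss <- joint_loss(b$y, out$v)
      if (!is.finite(loss))
        stop_fmt("non-finite training loss at epoch %d (lr=%g)", epoch, sched$lr)
      zero_grads(refs)
      backward(tape, out, joint_loss_grad(b$y, out$v))
      opt <- adam_step(refs, opt, sched$lr, cfg$weight_decay)
      tot <- tot + loss * length(idx)
    }
    train_loss <- tot / n
    val_loss <- eval_loss(net, val_set, cfg$batch_size)
    lr_now <- sched$lr
    sched <- schedule_step(sched, val_loss)
    if (sched$best_epoch == epoch) {
      best_w <- get_weights(net)
      best_bn <- get_bn_state(net)
    }
    log <- rbind(log, data.frame(epoch = epoch, train_loss = train_loss,
                                 val_loss = val_loss, lr = lr_now))
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f lr %g", epoch,
                      train_loss, val_loss, lr_now))
    if (sched$stop) break
  }
  if (!is.null(best_w)) {
    set_weights(net, best_w)
    set_bn_state(net, best_bn)
  }
  res <- list(log = log, best_epoch = sched$best_epoch,
              best_val_loss = sched$best, best_weights = best_w)
  class(res) <- "train_result"
  res
}

#' Run a fixed number of Adam steps on one small batch (overfit probe)
#'
#' Convenience used to verify that the network can fit a handful of patches.
#'
#' @param net a built network.
#' @param x,y input batch `[H,W,1,B]` and matching binary labels.
#' @param steps number of Adam steps.
#' @param lr learning rate.
#' @param weight_decay L2 penalty.
#' @return final training joint loss.
#' @export
overfit_batch <- function(net, x, y, steps = 200L, lr = 1e-3,
                          weight_decay = 1e-4) {
  refs <- collect_param_refs(unclass(net))
  opt <- adam_init(refs)
  loss <- NA_real_
  for (s in seq_len(steps)) {
    tape <- new_tape()
    out <- net_forward_node(net, x, tape = tape, training = TRUE)
    loss <- joint_loss(y, out$v)
    if (!is.finite(loss)) stop_fmt("non-finite loss at step %d", s)
    zero_grads(refs)
    backward(tape, out, joint_loss_grad(y, out$v))
    opt <- adam_step(refs, opt, lr, weight_decay)
  }
  loss
}
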