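# Minimal conv-net engine: layers hold parameters in environments, a forward
# tape records operations, and backward() replays it in reverse accumulating
# parameter gradients in the layer environments.
#
# Tensor layout everywhere: [H, W, C, B] (column-major, spatial fastest).

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

## ---- tape and nodes ---------------------------------------------------------

new_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$ops <- list()
  t
}

as_node <- function(v) {
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$grad <- NULL
  n
}

node_add_grad <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
  invisible(NULL)
}

tape_record <- function(tape, op) {
  if (!is.null(tape)) tape$ops[[length(tape$ops) + 1L]] <- op
  invisible(NULL)
}

## ---- layer constructors -----------------------------------------------------

# He (fan-in, ReLU gain) initialisation; weights packed [k*k*in_ch, out_ch].
nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = NULL, bias = FALSE) {
  l <- new.env(parent = emptyenv())
  l$kind <- "conv"
  l$in_ch <- as.integer(in_ch); l$out_ch <- as.integer(out_ch)
  l$k <- as.integer(k); l$stride <- as.integer(stride)
  l$pad <- as.integer(pad %||% ((k - 1L) %/% 2L))
  fan_in <- k * k * in_ch
  l$W <- matrix(stats::rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
                nrow = fan_in, ncol = out_ch)
  l$has_bias <- isTRUE(bias)
  l$b <- numeric(out_ch)
  l$dW <- NULL; l$db <- NULL
  class(l) <- c("nn_conv", "nn_layer")
  l
}

nn_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$kind <- "bn"
  l$ch <- as.integer(ch)
  l$gamma <- rep(1, ch); l$beta <- rep(0, ch)
  l$run_mean <- rep(0, ch); l$run_var <- rep(1, ch)
  l$momentum <- momentum; l$eps <- eps
  l$dgamma <- NULL; l$dbeta <- NULL
  class(l) <- c("nn_bn", "nn_layer")
  l
}

# residual fusion weights of the strip attention module, initialised at zero
nn_lambda <- function() {
  l <- new.env(parent = emptyenv())
  l$kind <- "lambda"
  l$l1 <- 0; l$l2 <- 0
  l$dl1 <- NULL; l$dl2 <- NULL
  class(l) <- c("nn_lambda", "nn_layer")
  l
}

zero_grads <- function(refs) {
  for (r in refs) r$env[[r$gfield]] <- r$env[[r$field]] * 0
  invisible(NULL)
}

# enumerate trainable parameters of a nested module list, in stable order
collect_param_refs <- function(x) {
  refs <- list()
  walk <- function(m) {
    if (inherits(m, "nn_layer")) {
      if (m$kind == "conv") {
        refs[[length(refs) + 1L]] <<- list(env = m, field = "W", gfield = "dW")
        if (m$has_bias)
          refs[[length(refs) + 1L]] <<- list(env = m, field = "b", gfield = "db")
      } else if (m$kind == "bn") {
        refs[[length(refs) + 1L]] <<- list(env = m, field = "gamma", gfield = "dgamma")
        refs[[length(refs) + 1L]] <<- list(env = m, field = "beta", gfield = "dbeta")
      } else if (m$kind == "lambda") {
        refs[[length(refs) + 1L]] <<- list(env = m, field = "l1", gfield = "dl1")
        refs[[length(refs) + 1L]] <<- list(env = m, field = "l2", gfield = "dl2")
      }
    } else if (is.list(m)) {
      for (el in m) walk(el)
    }
  }
  walk(x)
  refs
}

accum_layer_grad <- function(layer, gfield, g) {
  cur <- layer[[gfield]]
  layer[[gfield]] <- if (is.null(cur)) g else cur + g
  invisible(NULL)
}

## ---- primitive ops ----------------------------------------------------------

op_conv <- function(tape, x, layer) {
  d <- dim(x$v)
  if (d[3] != layer$in_ch)
    stop_fmt("conv expects %d input channels, got %d", layer$in_ch, d[3])
  y <- if (layer$k == 1L && layer$stride == 1L)
    conv1x1_fwd_cpp(x$v, layer$W, layer$b, d[1], d[2], d[3], d[4], layer$has_bias)
  else
    conv2d_fwd_cpp(x$v, layer$W, layer$b, d[1], d[2], d[3], d[4],
                   layer$k, layer$k, layer$stride, layer$pad, layer$has_bias)
  out <- as_node(y)
  tape_record(tape, list(op = "conv", x = x, out = out, layer = layer, xdim = d))
  out
}

bwd_conv <- function(rec) {
  dy <- rec$out$grad
  d <- rec$xdim
  l <- rec$layer
  res <- if (l$k == 1L && l$stride == 1L)
    conv1x1_bwd_cpp(rec$x$v, l$W, dy, d[1], d[2], d[3], d[4])
  else
    conv2d_bwd_cpp(rec$x$v, l$W, dy, d[1], d[2], d[3], d[4],
                   l$k, l$k, l$stride, l$pad)
  accum_layer_grad(l, "dW", res$dW)
  if (l$has_bias) accum_layer_grad(l, "db", res$db)
  node_add_grad(rec$x, res$dx)
}

op_bn <- function(tape, x, layer, training) {
  d <- dim(x$v); hw <- d[1] * d[2]
  if (training) {
    st <- bn_stats_cpp(x$v, hw, d[3], d[4])
    m <- hw * d[4]
    mu <- st$sum / m
    var <- pmax(st$sumsq / m - mu^2, 0)
    istd <- 1 / sqrt(var + layer$eps)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var  <- (1 - layer$momentum) * layer$run_var  + layer$momentum * var
  } else {
    istd <- 1 / sqrt(layer$run_var + layer$eps)
    mu <- layer$run_mean
  }
  # normalised values are recomputed from x in the backward pass, not cached
  out <- as_node(bn_apply_cpp(x$v, mu, istd, layer$gamma, layer$beta,
                              hw, d[3], d[4]))
  tape_record(tape, list(op = if (training) "bn_train" else "bn_eval",
                         x = x, out = out, layer = layer,
                         mu = mu, istd = istd, hw = hw, dim = d))
  out
}

bwd_bn <- function(rec) {
  l <- rec$layer; d <- rec$dim
  res <- bn_bwd_cpp(rec$x$v, rec$out$grad, rec$mu, rec$istd, l$gamma,
                    rec$hw, d[3], d[4], rec$op == "bn_train")
  accum_layer_grad(l, "dgamma", res$dgamma)
  accum_layer_grad(l, "dbeta", res$dbeta)
  node_add_grad(rec$x, res$dx)
}

op_relu <- function(tape, x) {
  out <- as_node(relu_fwd_cpp(x$v))
  tape_record(tape, list(op = "relu", x = x, out = out))
  out
}

bwd_relu <- function(rec) {
  node_add_grad(rec$x, relu_bwd_cpp(rec$out$v, rec$out$grad))
}

# fused batch-norm + ReLU (the standard block after every convolution)
op_bn_relu <- function(tape, x, layer, training) {
  d <- dim(x$v); hw <- d[1] * d[2]
  if (training) {
    st <- bn_stats_cpp(x$v, hw, d[3], d[4])
    m <- hw * d[4]
    mu <- st$sum / m
    var <- pmax(st$sumsq / m - mu^2, 0)
    istd <- 1 / sqrt(var + layer$eps)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var  <- (1 - layer$momentum) * layer$run_var  + layer$momentum * var
  } else {
    istd <- 1 / sqrt(layer$run_var + layer$eps)
    mu <- layer$run_mean
  }
  out <- as_node(bnrelu_fwd_cpp(x$v, mu, istd, layer$gamma, layer$beta,
                                hw, d[3], d[4]))
  tape_record(tape, list(op = if (training) "bnrelu_train" else "bnrelu_eval",
                         x = x, out = out, layer = layer,
                         mu = mu, istd = istd, hw = hw, dim = d))
  out
}

bwd_bn_relu <- function(rec) {
  l <- rec$layer; d <- rec$dim
  res <- bnrelu_bwd_cpp(rec$x$v, rec$out$v, rec$out$grad, rec$mu, rec$istd,
                        l$gamma, rec$hw, d[3], d[4], rec$op == "bnrelu_train")
  accum_layer_grad(l, "dgamma", res$dgamma)
  accum_layer_grad(l, "dbeta", res$dbeta)
  node_add_grad(rec$x, res$dx)
}

op_sigmoid <- function(tape, x) {
  y <- 1 / (1 + exp(-x$v))
  out <- as_node(y)
  tape_record(tape, list(op = "sigmoid", x = x, out = out, y = y))
  out
}

bwd_sigmoid <- function(rec) {
  node_add_grad(rec$x, rec$out$grad * rec$y * (1 - rec$y))
}

op_resize <- function(tape, x, oh, ow) {
  d <- dim(x$v)
  y <- resize_bilinear_fwd_cpp(x$v, d[1], d[2], d[3], d[4], oh, ow)
  out <- as_node(y)
  tape_record(tape, list(op = "resize", x = x, out = out, xdim = d,
                         oh = oh, ow = ow))
  out
}

bwd_resize <- function(rec) {
  d <- rec$xdim
  dx <- resize_bilinear_bwd_cpp(rec$out$grad, d[1], d[2], d[3], d[4],
                                rec$oh, rec$ow)
  node_add_grad(rec$x, dx)
}

op_add_n <- function(tape, nodes) {
  if (length(nodes) == 1L) return(nodes[[1L]])
  y <- nodes[[1L]]$v
  for (i in 2:length(nodes)) y <- y + nodes[[i]]$v
  out <- as_node(y)
  tape_record(tape, list(op = "add_n", xs = nodes, out = out))
  out
}

bwd_add_n <- function(rec) {
  for (x in rec$xs) node_add_grad(x, rec$out$grad)
}

# Z = X + lambda1 * O1 + lambda2 * O2  (Eq-3-style residual fusion)
op_lambda_add <- function(tape, x, o1, o2, lam) {
  y <- x$v + lam$l1 * o1$v + lam$l2 * o2$v
  out <- as_node(y)
  tape_record(tape, list(op = "lambda_add", x = x, o1 = o1, o2 = o2,
                         out = out, lam = lam))
  out
}

bwd_lambda_add <- function(rec) {
  dz <- rec$out$grad
  lam <- rec$lam
  accum_layer_grad(lam, "dl1", sum(dz * rec$o1$v))
  accum_layer_grad(lam, "dl2", sum(dz * rec$o2$v))
  node_add_grad(rec$x, dz)
  node_add_grad(rec$o1, lam$l1 * dz)
  node_add_grad(rec$o2, lam$l2 * dz)
}

## ---- axis attention core ----------------------------------------------------

# Attention over image columns (axis "w": one W x W matrix per sample) or
# rows (axis "h": H x H).  The heavy per-sample arithmetic lives in C++.
op_axis_attention <- function(tape, q, k, v, axis, mode) {
  d <- dim(q$v)
  r <- axis_att_fwd_cpp(q$v, k$v, v$v, d[1], d[2], d[3], d[4],
                        axis == "w", mode == "as_printed")
  out <- as_node(r$z)
  n <- if (axis == "w") d[2] else d[1]
  attr(out, "attention") <- lapply(seq_len(d[4]),
                                   function(b) matrix(r$A[, , b], n, n))
  tape_record(tape, list(op = "axis_att", q = q, k = k, v = v, out = out,
                         axis = axis, mode = mode, A = r$A, d = d))
  out
}

bwd_axis_attention <- function(rec) {
  d <- rec$d
  g <- axis_att_bwd_cpp(rec$q$v, rec$k$v, rec$v$v, rec$A, rec$out$grad,
                        d[1], d[2], d[3], d[4],
                        rec$axis == "w", rec$mode == "as_printed")
  node_add_grad(rec$q, g$dq)
  node_add_grad(rec$k, g$dk)
  node_add_grad(rec$v, g$dv)
}

## ---- backward dispatch ------------------------------------------------------

# Replays the tape in reverse.  To keep the peak memory bounded, every value
# and gradient is released as soon as the producing record has been
# processed (each consumer of a node appears later on the tape than its
# producer, so by then all consumers have run).  Node values on the tape are
# therefore unusable after backward().
backward <- function(tape, out_node, grad_out) {
  out_node$grad <- grad_out
  for (i in rev(seq_along(tape$ops))) {
    rec <- tape$ops[[i]]
    if (!is.null(rec$out$grad)) {
      switch(rec$op,
        conv        = bwd_conv(rec),
        bn_train    = bwd_bn(rec),
        bn_eval     = bwd_bn(rec),
        bnrelu_train = bwd_bn_relu(rec),
        bnrelu_eval  = bwd_bn_relu(rec),
        relu        = bwd_relu(rec),
        sigmoid     = bwd_sigmoid(rec),
        resize      = bwd_resize(rec),
        add_n       = bwd_add_n(rec),
        lambda_add  = bwd_lambda_add(rec),
        axis_att    = bwd_axis_attention(rec),
        stop_fmt("unknown op '%s'", rec$op))
    }
    rec$out$grad <- NULL
    rec$out$v <- NULL
    tape$ops[i] <- list(NULL)
  }
  invisible(NULL)
}

## ---- conv+BN+ReLU stack helper ---------------------------------------------

nn_cbr <- function(in_ch, out_ch, k, stride = 1L) {
  list(conv = nn_conv(in_ch, out_ch, k, stride), bn = nn_bn(out_ch))
}

cbr_fwd <- function(cbr, x, tape, training) {
  op_bn_relu(tape, op_conv(tape, x, cbr$conv), cbr$bn, training)
}
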