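# Three-stream high-resolution segmentation network.
#
# The main stream keeps the full H x W resolution with C channels from input
# to output; branch streams at H/2 x W/2 (2C channels) and H/4 x W/4 (4C) are
# created from the stream above by a stride-2 3x3 conv after stages 1 and 2.
# Every stage applies `convs_per_stage` 3x3 conv+BN+ReLU blocks per active
# stream; after each non-final stage a fusion block exchanges information
# across all active streams (down: chained stride-2 3x3 conv+BN+ReLU; up:
# bilinear upsample + 1x1 conv + BN), the fused sum passes a ReLU and then,
# on streams listed in `attention_streams`, a strip attention module.  The
# head performs a final all-to-high fusion and ends in a 1x1 conv + sigmoid.

STREAM_NAMES <- c("high", "medium", "low")

#' Network configuration
#'
#' @param base_channels channel count C of the full-resolution main stream;
#'   branch streams use 2C and 4C.
#' @param n_fusion_stages number of conv stages (each non-final stage is
#'   followed by a multi-resolution fusion block). At least 3 stages are
#'   needed for all three streams to exist.
#' @param convs_per_stage 3x3 conv+BN+ReLU blocks per stream per stage.
#' @param attention_enabled if `FALSE` the fusion blocks use plain addition
#'   (the ablation baseline: the same network with the strip attention
#'   modules removed).
#' @param attention_streams subset of `c("high","medium","low")` whose fused
#'   features pass through a strip attention module.
#' @param attention_softmax `"as_printed"` or `"over_keys"` (see
#'   [new_strip_attention_params()]).
#' @param input_channels channels of the network input (1 after
#'   preprocessing).
#' @param seed integer seed controlling weight initialisation.
#' @return object of class `network_config`.
#' @export
network_config <- function(base_channels = 16L, n_fusion_stages = 3L,
                           convs_per_stage = 2L, attention_enabled = TRUE,
                           attention_streams = c("high", "medium", "low"),
                           attention_softmax = c("as_printed", "over_keys"),
                           input_channels = 1L, seed = 1L) {
  attention_softmax <- match.arg(attention_softmax)
  if (base_channels < 1L) stop_fmt("base_channels must be >= 1")
  if (n_fusion_stages < 1L) stop_fmt("n_fusion_stages must be >= 1")
  if (convs_per_stage < 1L) stop_fmt("convs_per_stage must be >= 1")
  if (!all(attention_streams %in% STREAM_NAMES))
    stop_fmt("attention_streams must be a subset of high/medium/low")
  cfg <- list(base_channels = as.integer(base_channels),
              n_fusion_stages = as.integer(n_fusion_stages),
              convs_per_stage = as.integer(convs_per_stage),
              attention_enabled = isTRUE(attention_enabled),
              attention_streams = attention_streams,
              attention_softmax = attention_softmax,
              input_channels = as.integer(input_channels),
              seed = as.integer(seed))
  class(cfg) <- "network_config"
  cfg
}

stream_channels <- function(cfg) cfg$base_channels * c(high = 1L, medium = 2L, low = 4L)

#' Build the segmentation network
#'
#' Constructs all layers (deterministically for a fixed `cfg$seed`) without
#' running any data through them.  Spatial input sizes must be divisible by
#' `2^(n_streams - 1)` (4 for the full three-stream network) so the branch
#' resolutions are integral.
#'
#' @param cfg a [network_config()].
#' @return object of class `hr_network`.
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "network_config"))
  set.seed(cfg$seed)
  C <- stream_channels(cfg)
  n_streams <- min(cfg$n_fusion_stages, 3L)
  streams_at <- function(s) STREAM_NAMES[seq_len(min(s, n_streams))]

  new_att <- function(ch) new_strip_attention_params(ch, cfg$attention_softmax)

  stem <- nn_cbr(cfg$input_channels, C[["high"]], 3L)

  stages <- vector("list", cfg$n_fusion_stages)
  for (s in seq_len(cfg$n_fusion_stages)) {
    stages[[s]] <- lapply(stats::setNames(nm = streams_at(s)), function(st) {
      lapply(seq_len(cfg$convs_per_stage), function(i) nn_cbr(C[[st]], C[[st]], 3L))
    })
  }

  transitions <- list()
  for (s in seq_len(min(n_streams - 1L, cfg$n_fusion_stages - 1L))) {
    transitions[[STREAM_NAMES[s + 1L]]] <-
      nn_cbr(C[[STREAM_NAMES[s]]], C[[STREAM_NAMES[s + 1L]]], 3L, stride = 2L)
  }

  # fusion block after stage s (s < n_fusion_stages), over streams active
  # after the transition that follows stage s
  make_fusion <- function(active) {
    fu <- list(transforms = list(), att = list())
    for (dst in active) {
      for (src in active) {
        if (src == dst) next
        si <- match(src, STREAM_NAMES); di <- match(dst, STREAM_NAMES)
        key <- paste(src, dst, sep = "_to_")
        if (si > di) {          # lower resolution -> higher: upsample + 1x1 + BN
          fu$transforms[[key]] <- list(kind = "up",
                                       conv = nn_conv(C[[src]], C[[dst]], 1L),
                                       bn = nn_bn(C[[dst]]))
        } else {                # higher -> lower: chained stride-2 3x3 cbr
          steps <- lapply(seq_len(di - si), function(j) {
            ch_in <- C[[STREAM_NAMES[si + j - 1L]]]
            ch_out <- C[[STREAM_NAMES[si + j]]]
            nn_cbr(ch_in, ch_out, 3L, stride = 2L)
          })
          fu$transforms[[key]] <- list(kind = "down", steps = steps)
        }
      }
      if (cfg$attention_enabled && dst %in% cfg$attention_streams)
        fu$att[[dst]] <- new_att(C[[dst]])
    }
    fu
  }

  fusions <- list()
  for (s in seq_len(cfg$n_fusion_stages - 1L))
    fusions[[s]] <- make_fusion(streams_at(s + 1L))

  head <- list(up = list(), final = nn_conv(C[["high"]], 1L, 1L, bias = TRUE))
  final_active <- streams_at(cfg$n_fusion_stages)
  for (st in setdiff(final_active, "high"))
    head$up[[st]] <- list(conv = nn_conv(C[[st]], C[["high"]], 1L),
                          bn = nn_bn(C[["high"]]))
  if (cfg$attention_enabled && "high" %in% cfg$attention_streams)
    head$att <- new_att(C[["high"]])

  net <- list(cfg = cfg, stem = stem, stages = stages, transitions = transitions,
              fusions = fusions, head = head, n_streams = n_streams)
  class(net) <- "hr_network"
  net
}

stream_hw <- function(hw, stream) {
  f <- c(high = 1L, medium = 2L, low = 4L)[[stream]]
  hw %/% f
}

fusion_transform_fwd <- function(tr, x, dst_hw, tape, training) {
  if (tr$kind == "up") {
    y <- op_resize(tape, x, dst_hw[1], dst_hw[2])
    op_bn(tape, op_conv(tape, y, tr$conv), tr$bn, training)
  } else {
    y <- x
    for (st in tr$steps) y <- cbr_fwd(st, y, tape, training)
    y
  }
}

fusion_fwd <- function(fu, feats, hw, tape, training) {
  out <- list()
  for (dst in names(feats)) {
    dst_hw <- c(stream_hw(hw[1], dst), stream_hw(hw[2], dst))
    terms <- list(feats[[dst]])
    for (src in names(feats)) {
      if (src == dst) next
      key <- paste(src, dst, sep = "_to_")
      terms <- c(terms, list(fusion_transform_fwd(fu$transforms[[key]],
                                                  feats[[src]], dst_hw,
                                                  tape, training)))
    }
    y <- op_relu(tape, op_add_n(tape, terms))
    if (!is.null(fu$att[[dst]]))
      y <- strip_module_fwd(fu$att[[dst]], y, tape, training)
    out[[dst]] <- y
  }
  out
}

net_forward_node <- function(net, x, tape = NULL, training = FALSE) {
  cfg <- net$cfg
  d <- dim(x)
  if (length(d) != 4L)
    stop_fmt("input must be a [H, W, C, B] array")
  if (d[3] != cfg$input_channels)
    stop_fmt("network expects %d input channel(s), got %d", cfg$input_channels, d[3])
  div <- 2L^(net$n_streams - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop_fmt("input height and width must be divisible by %d", div)
  if (any(!is.finite(x))) stop_fmt("non-finite values in network input")
  hw <- d[1:2]

  feats <- list(high = cbr_fwd(net$stem, as_node(x), tape, training))
  for (s in seq_len(cfg$n_fusion_stages)) {
    for (st in names(feats))
      for (blk in net$stages[[s]][[st]])
        feats[[st]] <- cbr_fwd(blk, feats[[st]], tape, training)
    nxt <- STREAM_NAMES[s + 1L]
    if (s < net$n_streams && !is.null(net$transitions[[nxt]]))
      feats[[nxt]] <- cbr_fwd(net$transitions[[nxt]],
                              feats[[STREAM_NAMES[s]]], tape, training)
    if (s < cfg$n_fusion_stages)
      feats <- fusion_fwd(net$fusions[[s]], feats, hw, tape, training)
  }

  h <- feats$high
  if (length(feats) > 1L) {
    terms <- list(h)
    for (st in setdiff(names(feats), "high")) {
      up <- net$head$up[[st]]
      y <- op_resize(tape, feats[[st]], hw[1], hw[2])
      terms <- c(terms, list(op_bn(tape, op_conv(tape, y, up$conv), up$bn, training)))
    }
    h <- op_relu(tape, op_add_n(tape, terms))
  }
  if (!is.null(net$head$att))
    h <- strip_module_fwd(net$head$att, h, tape, training)
  op_sigmoid(tape, op_conv(tape, h, net$head$final))
}

#' Run the network forward
#'
#' @param net a built [build_network()] network.
#' @param batch array `[H, W, 1, B]` (values typically in `[0,1]`); height and
#'   width must be divisible by 4 for the three-stream network.
#' @param training if `TRUE` batch norm uses batch statistics and updates its
#'   running statistics.
#' @return probability array `[H, W, 1, B]`, all values strictly in (0, 1).
#' @export
net_forward <- function(net, batch, training = FALSE) {
  net_forward_node(net, batch, tape = NULL, training = training)$v
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: conv weights and biases, batch-norm
#' scales and shifts, and the attention fusion scalars.
#'
#' @param net a built network.
#' @return integer count.
#' @export
count_parameters <- function(net) {
  sum(vapply(collect_param_refs(unclass(net)),
             function(r) length(r$env[[r$field]]), numeric(1)))
}

#' Receptive field of a stack of stride-1 convolutions
#'
#' For odd square kernels with stride 1 and dilation 1 the receptive field is
#' `1 + sum(k - 1)`; two stacked 3x3 layers therefore see the same 5x5 window
#' as one 5x5 convolution.
#'
#' @param kernel_sizes integer vector of kernel sizes.
#' @return receptive field in pixels.
#' @export
receptive_field <- function(kernel_sizes) {
  if (length(kernel_sizes) == 0L) stop_fmt("kernel_sizes must be non-empty")
  if (any(kernel_sizes %% 2L == 0L)) stop_fmt("all kernels must be odd")
  1L + sum(as.integer(kernel_sizes) - 1L)
}

#' Flatten network weights to a numeric vector (stable order)
#' @param net a built network.
#' @return numeric vector of all trainable parameters.
#' @export
get_weights <- function(net) {
  unlist(lapply(collect_param_refs(unclass(net)),
                function(r) as.numeric(r$env[[r$field]])))
}

#' Overwrite network weights from a numeric vector produced by [get_weights()]
#' @param net a built network.
#' @param w numeric vector from [get_weights()] of a same-config network.
#' @return the network, invisibly (layers are modified in place).
#' @export
set_weights <- function(net, w) {
  refs <- collect_param_refs(unclass(net))
  pos <- 0L
  for (r in refs) {
    cur <- r$env[[r$field]]
    n <- length(cur)
    val <- w[(pos + 1L):(pos + n)]
    if (is.matrix(cur)) val <- matrix(val, nrow(cur), ncol(cur))
    r$env[[r$field]] <- val
    pos <- pos + n
  }
  if (pos != length(w)) stop_fmt("weight vector length mismatch")
  invisible(net)
}

# batch-norm running statistics, needed for exact checkpointing
get_bn_state <- function(net) {
  out <- list()
  walk <- function(m) {
    if (inherits(m, "nn_bn")) out[[length(out) + 1L]] <<- list(m$run_mean, m$run_var)
    else if (is.list(m) && !inherits(m, "nn_layer")) for (el in m) walk(el)
  }
  walk(unclass(net))
  out
}

set_bn_state <- function(net, state) {
  i <- 0L
  walk <- function(m) {
    if (inherits(m, "nn_bn")) {
      i <<- i + 1L
      m$run_mean <- state[[i]][[1L]]
      m$run_var <- state[[i]][[2L]]
    } else if (is.list(m) && !inherits(m, "nn_layer")) for (el in m) walk(el)
  }
  walk(unclass(net))
  invisible(net)
}
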