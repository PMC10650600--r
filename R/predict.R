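# Whole-image inference: preprocess -> overlap tiling -> network forward ->
# mean reconstruction; plus exact-rebuild checkpointing.

#' Save a model checkpoint
#'
#' Writes the weights, batch-norm running statistics and the full network
#' configuration to a single file, plus a JSON sidecar with the configuration
#' and seed for exact rebuilds.
#'
#' @param net a built network.
#' @param path checkpoint file path (RDS); the sidecar is `path` +
#'   `".json"`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(weights = get_weights(net), bn = get_bn_state(net),
               cfg = unclass(net$cfg)), path)
  jsonlite::write_json(c(unclass(net$cfg),
                         list(n_parameters = count_parameters(net))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a rebuilt `hr_network` with the stored weights.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  cfg <- do.call(network_config, ck$cfg)
  net <- build_network(cfg)
  set_weights(net, ck$weights)
  set_bn_state(net, ck$bn)
  net
}

#' Predict a whole-image vessel probability map
#'
#' Tiles the (preprocessed) image into overlapping patches, runs the network
#' in inference mode, and reconstructs the full-size probability map as the
#' per-pixel mean of all overlapping patch predictions.
#'
#' @param net a built (trained) network.
#' @param image preprocessed matrix `[H,W]` in `[0,1]`.
#' @param size patch side length (must match training; default 48).
#' @param stride tiling stride (smaller = more overlap, slower).
#' @param batch_size patches per forward pass.
#' @return probability matrix `[H,W]` with values in (0, 1).
#' @export
predict_map <- function(net, image, size = 48L, stride = 16L, batch_size = 64L) {
  grid <- tile_image(image, size = size, stride = stride)
  n <- dim(grid$patches)[3]
  preds <- array(0, dim = dim(grid$patches))
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    x <- grid$patches[, , idx, drop = FALSE]
    dim(x) <- c(size, size, 1L, length(idx))
    p <- net_forward(net, x, training = FALSE)
    preds[, , idx] <- p
  }
  reconstruct_from_patches(grid, preds)
}
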