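# Desk-scale learning experiments on synthetic phantoms: an overfit probe on
# a handful of patches and a small attention-vs-baseline comparison with a
# held-out phantom.  These back the package's end-to-end sanity checks and
# the acceptance script.

#' Overfit probe: fit a few patches with a small network
#'
#' Samples `n_patches` 48x48 patches from one phantom and runs `steps` Adam
#' steps of the joint loss on that fixed batch.  A working network/optimiser
#' pair drives the loss close to zero.
#'
#' @param seed integer seed (phantom, init and sampling).
#' @param n_patches patches in the batch.
#' @param steps Adam steps.
#' @param base_channels main-stream width C.
#' @return final joint training loss.
#' @export
overfit_probe <- function(seed = 1L, n_patches = 10L, steps = 200L,
                          base_channels = 8L) {
  cfg <- synthetic_config(seed = 1000L + seed)
  ph <- generate_phantom(cfg)
  pre <- preprocess(list(ph$image))[[1L]]
  ps <- sample_random_patches(pre, ph$label, n_patches, seed = seed)
  x <- ps$images; dim(x) <- c(48L, 48L, 1L, n_patches)
  y <- ps$labels; dim(y) <- c(48L, 48L, 1L, n_patches)
  net <- build_network(network_config(base_channels = base_channels,
                                      seed = seed))
  init_weights(net, seed)
  overfit_batch(net, x, y, steps = steps)
}

#' Train on synthetic phantoms and evaluate on a held-out phantom
#'
#' Generates `n_phantoms + 1` phantoms, trains on random patches from the
#' first `n_phantoms` (10% of patches held out as the validation set), and
#' returns the Dice coefficient of the binarised whole-image prediction on
#' the held-out phantom.
#'
#' @param seed seed for initialisation and shuffling.
#' @param data_seed seed for phantom generation and patch sampling.
#' @param attention build the strip-attention network (`TRUE`) or the
#'   plain-fusion baseline (`FALSE`).
#' @param n_phantoms training images.
#' @param patches_per_image random 48x48 patches sampled per image.
#' @param base_channels main-stream width C.
#' @param max_epochs epoch budget (the LR schedule and early stopping still
#'   apply within it).
#' @param stride tiling stride for the held-out prediction.
#' @return list with `dice`, `train_log`, `best_val_loss`.
#' @export
phantom_training_run <- function(seed = 1L, data_seed = 100L, attention = TRUE,
                                 n_phantoms = 20L, patches_per_image = 200L,
                                 base_channels = 8L, max_epochs = 1L,
                                 stride = 24L) {
  cfg <- synthetic_config()
  ds <- generate_dataset(cfg, n_phantoms + 1L, base_seed = data_seed)
  pre <- preprocess(lapply(ds, `[[`, "image"))
  sets <- lapply(seq_len(n_phantoms), function(i)
    sample_random_patches(pre[[i]], ds[[i]]$label, patches_per_image,
                          seed = data_seed * 13L + i, source_id = i))
  ps <- combine_patch_sets(sets)
  sp <- split_validation(ps, 0.1, seed = data_seed)
  net <- build_network(network_config(base_channels = base_channels,
                                      attention_enabled = attention,
                                      seed = seed))
  init_weights(net, seed)
  tcfg <- train_config(seed = seed, max_epochs = max_epochs)
  res <- train_network(net, sp$train, sp$val, tcfg)
  ho <- n_phantoms + 1L
  pm <- predict_map(net, pre[[ho]], stride = stride)
  list(dice = dice_coefficient(pm >= 0.5, ds[[ho]]$label > 0),
       train_log = res$log, best_val_loss = res$best_val_loss)
}
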