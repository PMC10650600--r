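# Run configuration: nested defaults mirroring each pipeline stage, YAML
# overrides with strict key validation, CLI flags on top.

#' Default run configuration
#'
#' Nested list of every pipeline knob with the published protocol as the
#' defaults: patch 48, 1000 patches/image, 10% validation, batch 64, Adam lr
#' 1e-3, weight decay 1e-4, Dice epsilon 1e-5, plateau/stop patience 5/20.
#'
#' @return nested named list (class `run_config`).
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1L,
    out_dir = "stripseg_run",
    synthetic = list(height = 584L, width = 565L, n_trees = 3L,
                     branch_prob = 0.02, width_min = 1, width_max = 20,
                     vessel_contrast = 0.35, illum_amplitude = 0.15,
                     noise_sd = 0.03, fov_radius_frac = 0.96),
    preprocessing = list(gray_mode = "luminance", clip_limit = 2.0,
                         tile_grid = 8L, gamma = 1.2, fov_threshold = 0.10),
    patching = list(n_per_image = 1000L, size = 48L, val_frac = 0.1),
    network = list(base_channels = 16L, n_fusion_stages = 3L,
                   convs_per_stage = 2L, attention_enabled = TRUE,
                   attention_streams = c("high", "medium", "low"),
                   attention_softmax = "as_printed", input_channels = 1L),
    training = list(batch_size = 64L, lr_init = 1e-3, weight_decay = 1e-4,
                    plateau_patience = 5L, stop_patience = 20L,
                    lr_factor = 0.5, max_epochs = 150L),
    evaluation = list(threshold = 0.5, stride = 16L, dice_epsilon = 1e-5)
  )
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override))
    stop_fmt("config field '%s' must be a mapping", path)
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    stop_fmt("unknown config key%s '%s'%s; valid keys: %s",
             if (length(bad) > 1) "s" else "",
             paste(file.path(path, bad), collapse = "', '"),
             "", paste(names(defaults), collapse = ", "))
  for (k in names(override)) {
    d <- defaults[[k]]
    o <- override[[k]]
    if (is.list(d) && !is.null(names(d))) {
      defaults[[k]] <- merge_config(d, o, file.path(path, k))
    } else {
      if (is.numeric(d) && !is.numeric(o))
        stop_fmt("config field '%s' must be numeric", file.path(path, k))
      if (is.character(d) && !is.character(o))
        stop_fmt("config field '%s' must be a string", file.path(path, k))
      defaults[[k]] <- if (is.integer(d) && is.numeric(o)) as.integer(o) else o
    }
  }
  defaults
}

#' Parse a YAML run configuration
#'
#' Reads a YAML file, checks every key against [default_run_config()]
#' (unknown keys are rejected with the list of valid keys), fills missing
#' fields with the defaults, and returns the merged configuration.  An empty
#' file yields the full default configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return `run_config` list.
#' @export
parse_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_fmt("config file '%s' not found", path)
  y <- yaml::read_yaml(path)
  if (is.null(y)) return(cfg)
  out <- merge_config(unclass(cfg), y)
  class(out) <- "run_config"
  out
}
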