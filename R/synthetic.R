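# Synthetic fundus phantoms: branching random-walk vessel trees (thin
# curvilinear structures, 1-20 px wide) drawn on a background with a smooth
# illumination gradient and Gaussian noise, inside a circular field of view.
# They stand in for real fundus photographs so the whole pipeline is testable
# without downloads; they are synthetic and make no attempt at photorealism.

#' Synthetic phantom configuration
#'
#' @param height,width image size in pixels (>= 48).
#' @param n_trees number of vessel trees to grow (0 gives an empty label).
#' @param branch_prob probability per walk step of spawning a side branch.
#' @param width_min,width_max vessel width bounds in pixels; widths are drawn
#'   per branch, uniformly within `[width_min, width_max]` (1 to 20 px covers
#'   the range seen in fundus photographs).
#' @param vessel_contrast intensity offset of vessels against the background,
#'   in `[0,1]` of the dynamic range. Positive values draw vessels darker than
#'   the background (as in the green channel of real fundus images); negative
#'   values draw them brighter.
#' @param illum_amplitude amplitude of the smooth illumination gradient, in
#'   `[0,1]`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   `[0,1]` units.
#' @param fov_radius_frac field-of-view radius as a fraction of
#'   `min(height, width)/2`.
#' @param seed integer seed; phantoms are bit-identical for identical
#'   configurations.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(height = 584L, width = 565L, n_trees = 3L,
                             branch_prob = 0.02, width_min = 1, width_max = 20,
                             vessel_contrast = 0.35, illum_amplitude = 0.15,
                             noise_sd = 0.03, fov_radius_frac = 0.96,
                             seed = 1L) {
  chk <- function(ok, field, msg) if (!ok) stop_fmt("invalid %s: %s", field, msg)
  chk(height >= 48, "height", "must be >= 48")
  chk(width >= 48, "width", "must be >= 48")
  chk(n_trees >= 0, "n_trees", "must be >= 0")
  chk(branch_prob >= 0 && branch_prob <= 1, "branch_prob", "must be in [0,1]")
  chk(width_min >= 1, "width_min", "must be >= 1")
  chk(width_max >= width_min, "width_max", "must be >= width_min")
  chk(width_max <= 20, "width_max", "must be <= 20")
  chk(abs(vessel_contrast) <= 1, "vessel_contrast", "must be in [-1,1]")
  chk(illum_amplitude >= 0 && illum_amplitude <= 1, "illum_amplitude", "must be in [0,1]")
  chk(noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(fov_radius_frac > 0 && fov_radius_frac <= 1, "fov_radius_frac", "must be in (0,1]")
  cfg <- list(height = as.integer(height), width = as.integer(width),
              n_trees = as.integer(n_trees), branch_prob = branch_prob,
              width_min = width_min, width_max = width_max,
              vessel_contrast = vessel_contrast,
              illum_amplitude = illum_amplitude, noise_sd = noise_sd,
              fov_radius_frac = fov_radius_frac, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# disc stamp offsets for a given real-valued radius; soft gives an
# anti-aliased profile in [0,1], hard a binary footprint
disc_offsets <- function(r) {
  ri <- ceiling(r + 1)
  g <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  d <- sqrt(g$dy^2 + g$dx^2)
  soft <- pmin(pmax(r + 0.5 - d, 0), 1)
  keep <- soft > 0
  list(dy = g$dy[keep], dx = g$dx[keep], soft = soft[keep],
       hard = (d <= r)[keep])
}

# grow one tree; returns data.frame(y, x, w) of centreline samples
grow_tree <- function(cfg, cy, cx, rad) {
  pts_y <- numeric(0); pts_x <- numeric(0); pts_w <- numeric(0)
  root_w <- stats::runif(1, cfg$width_min, cfg$width_max)
  ang0 <- stats::runif(1, 0, 2 * pi)
  start <- c(cy, cx) + stats::runif(2, -0.5, 0.5) * rad
  queue <- list(list(pos = start, dir = ang0, w = root_w,
                     len = stats::runif(1, 0.8, 1.6) * rad))
  n_branches <- 1L
  while (length(queue) > 0L && n_branches < 60L) {
    br <- queue[[1L]]; queue[[1L]] <- NULL
    pos <- br$pos; dir <- br$dir
    for (step in seq_len(ceiling(br$len))) {
      dir <- dir + stats::rnorm(1, 0, 0.08)
      pos <- pos + c(sin(dir), cos(dir))
      if (sqrt(sum((pos - c(cy, cx))^2)) > rad * 0.98) break
      pts_y <- c(pts_y, pos[1]); pts_x <- c(pts_x, pos[2]); pts_w <- c(pts_w, br$w)
      if (stats::runif(1) < cfg$branch_prob && br$w > cfg$width_min) {
        child_w <- stats::runif(1, cfg$width_min, br$w)
        side <- sample(c(-1, 1), 1L)
        queue[[length(queue) + 1L]] <-
          list(pos = pos, dir = dir + side * stats::runif(1, 0.3, 0.9),
               w = child_w, len = stats::runif(1, 0.3, 0.8) * rad)
        n_branches <- n_branches + 1L
      }
    }
  }
  data.frame(y = pts_y, x = pts_x, w = pts_w)
}

render_trees <- function(cfg, fov) {
  H <- cfg$height; W <- cfg$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad <- cfg$fov_radius_frac * min(H, W) / 2
  label <- matrix(FALSE, H, W)
  soft <- matrix(0, H, W)
  if (cfg$n_trees == 0L) return(list(label = label, soft = soft))
  pts <- do.call(rbind, lapply(seq_len(cfg$n_trees),
                               function(i) grow_tree(cfg, cy, cx, rad)))
  if (is.null(pts) || nrow(pts) == 0L) return(list(label = label, soft = soft))
  # quantise widths so stamp offsets can be cached
  wq <- round(pts$w * 2) / 2
  for (w in unique(wq)) {
    off <- disc_offsets((w - 1) / 2)
    sel <- which(wq == w)
    for (i in sel) {
      yy <- round(pts$y[i]) + off$dy
      xx <- round(pts$x[i]) + off$dx
      ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
      idx <- yy[ok] + (xx[ok] - 1L) * H
      label[idx[off$hard[ok]]] <- TRUE
      soft[idx] <- pmax(soft[idx], off$soft[ok])
    }
  }
  label <- label & fov
  soft[!fov] <- 0
  list(label = label, soft = soft)
}

#' Generate one synthetic vessel phantom
#'
#' Draws `n_trees` branching random-walk vessel trees inside a circular field
#' of view.  The binary label uses hard (non-anti-aliased) strokes so overlap
#' statistics are crisp; the image uses anti-aliased strokes, offset from the
#' background by `vessel_contrast`, over a smooth illumination gradient with
#' additive Gaussian noise.  If the vessel pixel fraction inside the FoV falls
#' outside (0, 0.5) the trees are redrawn (with a derived seed).
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `vessel_phantom`: list with `image` (`[H,W,3]`,
#'   values in `[0,255]`), `label` and `fov` (binary `[H,W]` matrices), and
#'   the generating `cfg`.
#' @export
generate_phantom <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  H <- cfg$height; W <- cfg$width
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  rad <- cfg$fov_radius_frac * min(H, W) / 2
  dy <- matrix(seq_len(H) - cy, H, W)
  dx <- matrix(rep(seq_len(W) - cx, each = H), H, W)
  fov <- (dy^2 + dx^2) <= rad^2

  set.seed(cfg$seed)
  tr <- render_trees(cfg, fov)
  if (cfg$n_trees > 0L) {
    attempt <- 0L
    repeat {
      frac <- sum(tr$label) / sum(fov)
      if (frac > 0 && frac < 0.5) break
      attempt <- attempt + 1L
      if (attempt > 20L) stop_fmt("could not reach a vessel fraction in (0,0.5)")
      set.seed(cfg$seed + 100003L * attempt)
      tr <- render_trees(cfg, fov)
    }
  }

  # smooth illumination: tilted plane plus an off-centre radial falloff
  u <- dy / H; v <- dx / W
  illum <- cfg$illum_amplitude *
    (0.6 * (u * stats::runif(1, -1, 1) + v * stats::runif(1, -1, 1)) +
     0.4 * exp(-((u - stats::runif(1, -0.3, 0.3))^2 +
                 (v - stats::runif(1, -0.3, 0.3))^2) / 0.18) - 0.2)
  bg <- 0.55 + illum
  g <- bg - cfg$vessel_contrast * tr$soft
  if (cfg$noise_sd > 0) g <- g + matrix(stats::rnorm(H * W, 0, cfg$noise_sd), H, W)
  g <- pmin(pmax(g, 0), 1)
  rgb <- array(0, dim = c(H, W, 3))
  rgb[, , 1] <- 0.88 * bg + 0.12          # bright red channel (FoV detection)
  rgb[, , 2] <- g                         # green carries the vessel contrast
  rgb[, , 3] <- 0.45 * g
  fovmul <- ifelse(fov, 1, 0.02)
  for (k in 1:3) rgb[, , k] <- pmin(pmax(rgb[, , k] * fovmul, 0), 1) * 255

  out <- list(image = rgb, label = (tr$label) * 1L, fov = fov * 1L, cfg = cfg)
  class(out) <- "vessel_phantom"
  out
}

#' Generate a list of phantoms
#'
#' Image `i` uses seed `base_seed + i`; list order is stable and calls with
#' identical arguments return identical lists.
#'
#' @param cfg a [synthetic_config()] (its `seed` field is ignored).
#' @param n_images number of phantoms (>= 1).
#' @param base_seed integer; phantom `i` is generated with seed
#'   `base_seed + i`.
#' @return list of `vessel_phantom` objects.
#' @export
generate_dataset <- function(cfg, n_images, base_seed = 0L) {
  if (n_images < 1) stop_fmt("invalid n_images: must be >= 1")
  lapply(seq_len(n_images), function(i) {
    ci <- cfg
    ci$seed <- as.integer(base_seed + i)
    generate_phantom(ci)
  })
}

#' Write a phantom as PNG files
#'
#' Writes `{stem}.png` (RGB image), `{stem}_label.png` and `{stem}_fov.png`
#' (binary masks).
#'
#' @param ph a `vessel_phantom`.
#' @param stem output path prefix (without extension).
#' @return paths of the written files, invisibly.
#' @export
write_phantom <- function(ph, stem) {
  stopifnot(inherits(ph, "vessel_phantom"))
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  paths <- paste0(stem, c(".png", "_label.png", "_fov.png"))
  png::writePNG(ph$image / 255, paths[1])
  png::writePNG(ph$label + 0, paths[2])
  png::writePNG(ph$fov + 0, paths[3])
  invisible(paths)
}
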