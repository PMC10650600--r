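# Fundus preprocessing chain: RGB -> gray -> dataset-wide normalisation ->
# CLAHE -> gamma correction, and FoV-mask estimation for datasets without
# masks.  Every stage maps [0,255] -> [0,255]; the assembled pipeline rescales
# its final output to [0,1] for the network.

set_stage <- function(img, stage) { attr(img, "stage") <- stage; img }

#' Image provenance tag
#' @param img an image processed by the preprocessing functions.
#' @return the stage tag (`raw`, `gray`, `normalized`, `clahe` or `gamma`).
#' @export
image_stage <- function(img) attr(img, "stage") %||% "raw"

#' RGB to gray conversion
#'
#' ITU-R 601 luminance `0.299 R + 0.587 G + 0.114 B`, or the green channel
#' alone (`mode = "green"`), which is common in fundus work because vessel
#' contrast is strongest there.
#'
#' @param img array `[H,W,3]` with intensities in `[0,255]`, or an already
#'   gray matrix (returned unchanged with a warning).
#' @param mode `"luminance"` or `"green"`.
#' @return gray matrix `[H,W]` in `[0,255]`, stage-tagged `"gray"`.
#' @export
rgb_to_gray <- function(img, mode = c("luminance", "green")) {
  mode <- match.arg(mode)
  if (length(dim(img)) == 2L) {
    warning("input is already gray; returning unchanged")
    return(set_stage(img, "gray"))
  }
  if (length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_fmt("expected an [H,W,3] RGB array")
  g <- if (mode == "luminance")
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  else img[, , 2]
  set_stage(pmin(pmax(g, 0), 255), "gray")
}

#' Dataset-wide intensity normalisation
#'
#' Z-scores all images with the global (dataset-wide) mean and standard
#' deviation, then affinely rescales the whole set to span `[0, 255]`.
#'
#' @param imgs list of gray matrices in `[0,255]`.
#' @return list of matrices, global min 0 and max 255, stage `"normalized"`.
#' @export
standardize <- function(imgs) {
  if (!is.list(imgs) || length(imgs) < 1L) stop_fmt("need at least one image")
  all_v <- unlist(imgs, use.names = FALSE)
  mu <- mean(all_v); sd <- stats::sd(all_v)
  if (sd == 0) stop_fmt("constant dataset: global standard deviation is zero")
  z <- lapply(imgs, function(im) (im - mu) / sd)
  lo <- min(vapply(z, min, numeric(1))); hi <- max(vapply(z, max, numeric(1)))
  lapply(z, function(im) set_stage((im - lo) / (hi - lo) * 255, "normalized"))
}

#' Contrast-limited adaptive histogram equalisation
#'
#' Tile-wise histogram equalisation with a clip limit that bounds noise
#' amplification (computed by `EBImage::clahe`).  CLAHE is not idempotent:
#' applying it twice generally differs from applying it once.
#'
#' @param img gray matrix in `[0,255]`.
#' @param clip_limit contrast clip limit (values around 2 are conventional
#'   for fundus images).
#' @param tile_grid number of tiles per image side.
#' @return gray matrix in `[0,255]`, stage `"clahe"`.
#' @export
apply_clahe <- function(img, clip_limit = 2.0, tile_grid = 8L) {
  d <- dim(img)
  if (tile_grid > min(d)) stop_fmt("tile grid (%d) larger than image (%dx%d)",
                                   tile_grid, d[1], d[2])
  # the tiling requires dimensions divisible by the grid: reflect-pad, crop back
  ph <- (tile_grid - d[1] %% tile_grid) %% tile_grid
  pw <- (tile_grid - d[2] %% tile_grid) %% tile_grid
  padded <- reflect_pad(unclass(img), ph, pw)
  y <- EBImage::clahe(EBImage::Image(t(padded) / 255),
                      nx = tile_grid, ny = tile_grid, limit = clip_limit)
  out <- t(EBImage::imageData(y))[seq_len(d[1]), seq_len(d[2])] * 255
  set_stage(pmin(pmax(out, 0), 255), "clahe")
}

#' Gamma correction
#'
#' `out = 255 * (in/255)^gamma`; gamma > 1 darkens mid-tones, gamma < 1
#' brightens them.
#'
#' @param img gray matrix in `[0,255]`.
#' @param gamma exponent, must be > 0.
#' @return gray matrix in `[0,255]`, stage `"gamma"`.
#' @export
gamma_correct <- function(img, gamma = 1.2) {
  if (gamma <= 0) stop_fmt("invalid gamma: must be > 0")
  set_stage(255 * (pmin(pmax(img, 0), 255) / 255)^gamma, "gamma")
}

#' Full preprocessing pipeline
#'
#' Applies, in order: [rgb_to_gray()], [standardize()] (dataset-wide),
#' [apply_clahe()], [gamma_correct()]; the result is rescaled to `[0,1]` as
#' network input.  The pipeline is fully deterministic.
#'
#' @param imgs list of RGB arrays `[H,W,3]` in `[0,255]`.
#' @param gray_mode `"luminance"` or `"green"`.
#' @param clip_limit,tile_grid CLAHE parameters.
#' @param gamma gamma-correction exponent.
#' @return list of matrices in `[0,1]`, stage `"gamma"`.
#' @export
preprocess <- function(imgs, gray_mode = "luminance", clip_limit = 2.0,
                       tile_grid = 8L, gamma = 1.2) {
  if (!is.list(imgs)) imgs <- list(imgs)
  gs <- lapply(imgs, rgb_to_gray, mode = gray_mode)
  ns <- standardize(gs)
  cs <- lapply(ns, apply_clahe, clip_limit = clip_limit, tile_grid = tile_grid)
  gm <- lapply(cs, gamma_correct, gamma = gamma)
  lapply(gm, function(im) set_stage(im / 255, "gamma"))
}

#' Estimate a field-of-view mask from an RGB fundus image
#'
#' Thresholds the normalised red channel, applies a morphological closing,
#' keeps the largest connected component and fills its holes.
#'
#' @param img RGB array `[H,W,3]` in `[0,255]`.
#' @param threshold threshold on the red channel after division by 255.
#' @return binary matrix `[H,W]`.
#' @export
estimate_fov_mask <- function(img, threshold = 0.10) {
  if (length(dim(img)) != 3L) stop_fmt("expected an RGB array")
  red <- img[, , 1] / 255
  m <- red >= threshold
  if (!any(m))
    stop_fmt("empty FoV mask at threshold %.3f; try a lower threshold", threshold)
  eb <- EBImage::Image(t(m * 1))
  # small brush: bridge boundary nicks without eroding the disc edge
  # (interior holes are handled by fillHull below)
  eb <- EBImage::closing(eb, EBImage::makeBrush(3, shape = "disc"))
  lab <- EBImage::bwlabel(eb)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0L || max(tab) == 0L)
    stop_fmt("empty FoV mask after morphology; try a lower threshold")
  keep <- which.max(tab)
  comp <- EBImage::Image((EBImage::imageData(lab) == keep) * 1)
  comp <- EBImage::fillHull(comp)
  t(EBImage::imageData(comp)) * 1
}
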