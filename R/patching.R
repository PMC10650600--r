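# Random 48x48 patch sampling for training and deterministic overlap tiling
# plus exact reconstruction for whole-image inference.  Coordinates are
# 0-based, origin = top-left, row-major patch ordering.

#' Sample random training patches from one image
#'
#' Draws `n` patch origins uniformly over all valid positions (the patch must
#' lie fully inside the image) and cuts image and label patches at identical
#' origins.  Deterministic for a fixed seed.
#'
#' @param image numeric matrix `[H,W]` (typically preprocessed, in `[0,1]`).
#' @param label binary matrix `[H,W]`.
#' @param n number of patches.
#' @param size patch side length in pixels (default 48).
#' @param seed integer seed.
#' @param source_id identifier stored with each patch.
#' @return object of class `patch_set`: `images` and `labels` arrays
#'   `[size, size, n]`, `origins` (n x 2 matrix of 0-based row/col), `source`,
#'   `split` tag.
#' @export
sample_random_patches <- function(image, label, n, size = 48L, seed = 1L,
                                  source_id = 1L) {
  d <- dim(image)
  if (!all(d == dim(label))) stop_fmt("image and label shapes differ")
  if (d[1] < size || d[2] < size)
    stop_fmt("image (%dx%d) smaller than patch size %d", d[1], d[2], size)
  set.seed(seed)
  rows <- sample.int(d[1] - size + 1L, n, replace = TRUE) - 1L
  cols <- sample.int(d[2] - size + 1L, n, replace = TRUE) - 1L
  imgs <- array(0, dim = c(size, size, n))
  labs <- array(0, dim = c(size, size, n))
  for (i in seq_len(n)) {
    ri <- rows[i] + seq_len(size); ci <- cols[i] + seq_len(size)
    imgs[, , i] <- image[ri, ci]
    labs[, , i] <- label[ri, ci]
  }
  ps <- list(images = imgs, labels = labs,
             origins = cbind(row = rows, col = cols),
             source = rep(as.integer(source_id), n), split = "train")
  class(ps) <- "patch_set"
  ps
}

#' Combine patch sets
#' @param ... `patch_set` objects.
#' @return a single `patch_set` with patches concatenated in argument order.
#' @export
combine_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !inherits(sets[[1]], "patch_set"))
    sets <- sets[[1]]
  ps <- list(images = do.call(abind3, lapply(sets, `[[`, "images")),
             labels = do.call(abind3, lapply(sets, `[[`, "labels")),
             origins = do.call(rbind, lapply(sets, `[[`, "origins")),
             source = unlist(lapply(sets, `[[`, "source")),
             split = sets[[1]]$split)
  class(ps) <- "patch_set"
  ps
}

abind3 <- function(...) {
  parts <- list(...)
  d <- dim(parts[[1]])[1:2]
  n <- sum(vapply(parts, function(a) dim(a)[3], numeric(1)))
  out <- array(0, dim = c(d, n))
  pos <- 0L
  for (a in parts) {
    k <- dim(a)[3]
    out[, , pos + seq_len(k)] <- a
    pos <- pos + k
  }
  out
}

n_patches <- function(ps) dim(ps$images)[3]

patch_subset <- function(ps, idx, split) {
  out <- list(images = ps$images[, , idx, drop = FALSE],
              labels = ps$labels[, , idx, drop = FALSE],
              origins = ps$origins[idx, , drop = FALSE],
              source = ps$source[idx], split = split)
  class(out) <- "patch_set"
  out
}

#' Split a patch set into training and validation subsets
#'
#' Selects `round(frac * n)` patches (uniformly, deterministic per seed) as
#' the validation set; the split is a partition: disjoint, union = input.
#'
#' @param ps a `patch_set`.
#' @param frac validation fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train` and `val` patch sets.
#' @export
split_validation <- function(ps, frac = 0.1, seed = 1L) {
  if (frac <= 0 || frac >= 1) stop_fmt("invalid frac: must be in (0,1)")
  n <- n_patches(ps)
  n_val <- round(frac * n)
  set.seed(seed)
  val_idx <- sort(sample.int(n, n_val))
  train_idx <- setdiff(seq_len(n), val_idx)
  list(train = patch_subset(ps, train_idx, "train"),
       val = patch_subset(ps, val_idx, "val"))
}

#' Tile an image into an overlapping patch grid
#'
#' Reflect-pads the image on the bottom/right so a stride-`stride` grid of
#' `size x size` patches covers it exactly, then cuts patches in row-major
#' order.  The grid geometry is kept so [reconstruct_from_patches()] can
#' invert the operation exactly.
#'
#' @param image numeric matrix `[H,W]`.
#' @param size patch side length.
#' @param stride grid stride, `1 <= stride <= size`.
#' @return object of class `patch_grid`.
#' @export
tile_image <- function(image, size = 48L, stride = 16L) {
  if (stride < 1L) stop_fmt("stride must be >= 1")
  if (stride > size) stop_fmt("stride must be <= patch size")
  d <- dim(image)
  pad_len <- function(n) {
    if (n <= size) size - n
    else (stride - ((n - size) %% stride)) %% stride
  }
  ph <- pad_len(d[1]); pw <- pad_len(d[2])
  padded <- reflect_pad(image, ph, pw)
  dp <- dim(padded)
  r0 <- seq(0L, dp[1] - size, by = stride)
  c0 <- seq(0L, dp[2] - size, by = stride)
  n <- length(r0) * length(c0)
  patches <- array(0, dim = c(size, size, n))
  origins <- matrix(0L, n, 2L)
  i <- 0L
  for (r in r0) for (cc in c0) {     # row-major: row varies slowest
    i <- i + 1L
    patches[, , i] <- padded[r + seq_len(size), cc + seq_len(size)]
    origins[i, ] <- c(r, cc)
  }
  g <- list(patches = patches, origins = origins, size = as.integer(size),
            stride = as.integer(stride), orig_dim = d, padded_dim = dp)
  class(g) <- "patch_grid"
  g
}

reflect_pad <- function(m, ph, pw) {
  d <- dim(m)
  if (ph > 0) {
    if (ph > d[1] - 1L) stop_fmt("reflect padding larger than image")
    m <- rbind(m, m[d[1] - seq_len(ph), , drop = FALSE])
  }
  if (pw > 0) {
    if (pw > d[2] - 1L) stop_fmt("reflect padding larger than image")
    m <- cbind(m, m[, d[2] - seq_len(pw), drop = FALSE])
  }
  m
}

#' Reconstruct a full-size map from (predicted) patches
#'
#' Every pixel of the padded extent is the mean of all patch predictions that
#' cover it; the padding is then cropped, giving a map of the original image
#' shape.  With the identity predictor this inverts [tile_image()] exactly.
#'
#' @param grid a `patch_grid` whose `patches` slot holds prediction patches
#'   (same geometry as produced by [tile_image()]).
#' @param patches optional replacement array `[size,size,n]` of predicted
#'   patches; defaults to `grid$patches`.
#' @return numeric matrix of the original image shape.
#' @export
reconstruct_from_patches <- function(grid, patches = NULL) {
  stopifnot(inherits(grid, "patch_grid"))
  patches <- patches %||% grid$patches
  if (!all(dim(patches) == dim(grid$patches)))
    stop_fmt("patch array geometry does not match the grid")
  dp <- grid$padded_dim
  acc <- matrix(0, dp[1], dp[2])
  cnt <- matrix(0, dp[1], dp[2])
  s <- grid$size
  for (i in seq_len(dim(patches)[3])) {
    ri <- grid$origins[i, 1] + seq_len(s)
    ci <- grid$origins[i, 2] + seq_len(s)
    acc[ri, ci] <- acc[ri, ci] + patches[, , i]
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  (acc / cnt)[seq_len(grid$orig_dim[1]), seq_len(grid$orig_dim[2])]
}
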