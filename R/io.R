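# Image reading/writing.  PNG and TIFF go through the png/tiff packages; PPM
# (the STARE distribution format) has no reader in the installed stack, so a
# small one lives here (P2/P3 ascii and P5/P6 binary).

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- character(0)
  # header tokens: magic, width, height, maxval (P1/P4 bitmaps not supported)
  while (length(tok) < 4L) {
    line <- readLines(con, n = 1L)
    line <- sub("#.*", "", line)
    tok <- c(tok, strsplit(trimws(line), "\\s+")[[1]])
    tok <- tok[nzchar(tok)]
  }
  magic <- tok[1]
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxv <- as.integer(tok[4])
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    if (maxv > 255) stop_fmt("16-bit PPM not supported")
    as.integer(readBin(con, "raw", n = n))
  } else if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else stop_fmt("unsupported PPM magic '%s'", magic)
  # pixel order: row-major, channels interleaved
  if (nch == 3L) {
    a <- aperm(array(vals, dim = c(3L, w, h)), c(3L, 2L, 1L))
  } else {
    a <- t(array(vals, dim = c(w, h)))
    dim(a) <- c(h, w, 1L)
  }
  a / maxv * 255
}

#' Read an image file (PNG, TIFF or PPM/PGM)
#'
#' @param path file path; format chosen by extension.
#' @return array `[H,W,C]` (or `[H,W]` for single-channel PNG/TIFF) with
#'   intensities in `[0,255]`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  out <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path) * 255,
    ppm = ,
    pgm = read_ppm(path),
    stop_fmt("unsupported image format '.%s'", ext))
  if (length(dim(out)) == 3L && dim(out)[3] == 1L) dim(out) <- dim(out)[1:2]
  if (length(dim(out)) == 3L && dim(out)[3] == 4L) out <- out[, , 1:3]  # drop alpha
  out
}

#' Write a probability map
#'
#' Writes the map at 16-bit depth as TIFF plus an 8-bit PNG preview, and a
#' 0.5-thresholded binary PNG.
#'
#' @param p_map probability matrix in `[0,1]`.
#' @param stem output path prefix.
#' @param threshold binarisation threshold for the mask output.
#' @return written paths, invisibly.
#' @export
write_probability_map <- function(p_map, stem, threshold = 0.5) {
  dir.create(dirname(stem), showWarnings = FALSE, recursive = TRUE)
  paths <- paste0(stem, c("_prob.tiff", "_prob.png", "_bin.png"))
  tiff::writeTIFF(pmin(pmax(p_map, 0), 1), paths[1], bits.per.sample = 16L)
  png::writePNG(pmin(pmax(p_map, 0), 1), paths[2])
  png::writePNG((p_map >= threshold) * 1, paths[3])
  invisible(paths)
}
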