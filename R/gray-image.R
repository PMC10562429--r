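#' Calibrated grayscale image
#'
#' A `gray_image` is a plain numeric matrix (rows = y, columns = x, pixel
#' centers at integer coordinates) carrying a pixel calibration in micrometers
#' per pixel and a polarity flag saying whether the biological signal is
#' brighter (`"signal_bright"`, fluorescence) or darker (`"signal_dark"`,
#' DAB-type chromogenic stain) than the background.
#'
#' @param pixels Numeric matrix of intensities, or a `gray_image`.
#' @param pixel_size_um Pixel size in micrometers per pixel (> 0).
#' @param polarity One of `"signal_bright"`, `"signal_dark"`.
#' @return A `gray_image` object.
#' @export
gray_image <- function(pixels, pixel_size_um = 1, polarity = c("signal_bright", "signal_dark")) {
  polarity <- match.arg(polarity)
  if (inherits(pixels, "gray_image")) {
    pixels$polarity <- polarity
    if (!missing(pixel_size_um)) pixels$pixel_size_um <- pixel_size_um
    return(pixels)
  }
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    abort("image intensities must be finite")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 || pixel_size_um <= 0)
    abort("`pixel_size_um` must be a single positive number")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um, polarity = polarity),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, %.4g um/px, %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$polarity))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Coerce matrix or gray_image to an intensity matrix
img_pixels <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img) && is.numeric(img)) img
  else abort("expected a numeric matrix or a gray_image")
}

img_pixel_size <- function(img, default = 1) {
  if (inherits(img, "gray_image") || inherits(img, "label_map")) img$pixel_size_um
  else default
}

#' Labeled segmentation map
#'
#' Integer raster on the same grid as its source image; 0 is background and
#' each positive label is one 8-connected cell.
#'
#' @param labels Integer matrix (0 = background).
#' @param pixel_size_um Pixel size in micrometers per pixel.
#' @return A `label_map` object.
#' @export
label_map <- function(labels, pixel_size_um = 1) {
  if (!is.matrix(labels)) abort("`labels` must be a matrix")
  storage.mode(labels) <- "integer"
  if (any(labels < 0, na.rm = TRUE)) abort("labels must be non-negative")
  structure(list(labels = labels, pixel_size_um = pixel_size_um), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d cells, %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), n_labels(x), x$pixel_size_um))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

lab_pixels <- function(x) {
  if (inherits(x, "label_map")) x$labels
  else if (is.matrix(x)) { storage.mode(x) <- "integer"; x }
  else abort("expected an integer matrix or a label_map")
}

#' Number of distinct cells in a label map
#' @param x A `label_map` or integer matrix.
#' @return Integer count of nonzero labels.
#' @export
n_labels <- function(x) {
  m <- lab_pixels(x)
  length(setdiff(unique(as.vector(m)), 0L))
}

# Relabel nonzero labels to 1..n preserving first-appearance (raster) order
relabel_contiguous <- function(labels) {
  m <- lab_pixels(labels)
  ids <- setdiff(unique(as.vector(m)), 0L)
  if (length(ids) == 0) return(m)
  lut <- integer(max(ids) + 1L)
  lut[ids + 1L] <- seq_along(ids)
  out <- m
  nz <- m != 0L
  out[nz] <- lut[m[nz] + 1L]
  out
}

# 8-connected labelling of a logical mask (raster discovery order)
label8 <- function(mask) {
  stopifnot(is.matrix(mask))
  cpp_label8(matrix(as.logical(mask), nrow(mask), ncol(mask)))
}

#' Read / write grayscale TIFF images
#'
#' Thin wrappers over the tiff package. Stacks are read as a list of matrices
#' (one per frame) and written the same way.
#'
#' @param path File path.
#' @param pixel_size_um Calibration attached to the image on read.
#' @param polarity Signal polarity attached on read.
#' @return `read_gray_tiff()` returns a `gray_image`; `read_stack_tiff()` a
#'   list of matrices.
#' @export
read_gray_tiff <- function(path, pixel_size_um = 1, polarity = "signal_bright") {
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3) px <- rgb_to_gray(px)
  gray_image(px, pixel_size_um, polarity)
}

#' @rdname read_gray_tiff
#' @param img Image (matrix or `gray_image`) to write; intensities are scaled
#'   to \[0, 1\] for storage.
#' @export
write_gray_tiff <- function(img, path) {
  px <- img_pixels(img)
  rng <- range(px)
  scaled <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname read_gray_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  frames
}

#' @rdname read_gray_tiff
#' @param frames List of matrices (one per frame).
#' @export
write_stack_tiff <- function(frames, path) {
  rng <- range(unlist(lapply(frames, range)))
  scaled <- lapply(frames, function(f) {
    if (diff(rng) > 0) (f - rng[1]) / diff(rng) else f * 0
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16)
  invisible(path)
}

# ITU-R 601 luminance conversion of an H x W x 3 array
rgb_to_gray <- function(arr) {
  0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
}
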