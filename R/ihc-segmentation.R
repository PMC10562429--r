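# Two-stage segmentation of stained-section microglia: darker-stained somata
# are detected as area-thresholded supra-Th1 components, then cells are grown
# by a seeded watershed restricted to pixels above Th2. Structures not
# connected to any soma seed stay background, which deliberately drops
# branches of cells whose somata lie outside the section.

#' Segmentation parameters for stained-section images
#'
#' Th1 (soma seed threshold) is `I_max - f1 * I_SD`, Th2 (watershed floor) is
#' `I_mean + f2 * I_SD`, both measured on the preprocessed image. `f1` and
#' `f2` are dataset-specific factors tuned empirically per staining batch.
#'
#' @param f1 Seed-threshold factor (>= 0), default 2.
#' @param f2 Watershed-threshold factor (>= 0), default 0.5.
#' @param seed_area_threshold_px Minimum soma-seed area, pixels (default 300).
#' @param min_cell_area_px Cells must be strictly larger than this, pixels
#'   (default 900).
#' @param rolling_ball_radius_px Background-subtraction radius, pixels
#'   (default 50).
#' @param gaussian_sigma_px Smoothing sigma, pixels (default 1).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(f1 = 2, f2 = 0.5, seed_area_threshold_px = 300,
                                min_cell_area_px = 900, rolling_ball_radius_px = 50,
                                gaussian_sigma_px = 1) {
  p <- list(f1 = f1, f2 = f2, seed_area_threshold_px = seed_area_threshold_px,
            min_cell_area_px = min_cell_area_px,
            rolling_ball_radius_px = rolling_ball_radius_px,
            gaussian_sigma_px = gaussian_sigma_px)
  if (f1 < 0 || f2 < 0) abort("`f1` and `f2` must be non-negative")
  if (any(unlist(p[3:6]) <= 0)) abort("thresholds, radius and sigma must be positive")
  structure(p, class = "segmentation_params")
}

#' Preprocess a raw stained-section image
#'
#' Converts RGB to 8-bit grayscale (ITU-R 601 luminance), inverts dark-stain
#' images so the signal is bright, removes smooth background with a
#' rolling-ball (grayscale opening with a disc of the given radius) and
#' smooths with a Gaussian.
#'
#' @param raw Numeric matrix, H x W x 3 array, or [gray_image()].
#' @param params [segmentation_params()].
#' @param polarity Signal polarity of the input when `raw` is a bare
#'   matrix/array; `gray_image` inputs carry their own.
#' @param pixel_size_um Calibration for bare matrix inputs.
#' @return A `gray_image` with `signal_bright` polarity on a 0-255 scale.
#' @export
preprocess <- function(raw, params = segmentation_params(),
                       polarity = c("signal_dark", "signal_bright"),
                       pixel_size_um = 1) {
  if (inherits(raw, "gray_image")) {
    polarity <- raw$polarity
    pixel_size_um <- raw$pixel_size_um
    px <- raw$pixels
  } else {
    polarity <- match.arg(polarity)
    if (is.array(raw) && length(dim(raw)) == 3) px <- rgb_to_gray(raw)
    else px <- raw
    if (!is.matrix(px) || !is.numeric(px)) abort("`raw` must be a 2D image")
  }
  if (length(px) == 0 || !any(is.finite(px))) abort("empty or all-NaN image")
  # to 8-bit scale
  if (max(px) <= 1) px <- px * 255
  px <- pmin(pmax(px, 0), 255)
  if (polarity == "signal_dark") px <- 255 - px
  # rolling-ball background: grayscale opening with a disc structuring element
  # (EBImage grayscale morphology operates on the [0, 1] scale)
  r <- params$rolling_ball_radius_px
  brush <- EBImage::makeBrush(2 * floor(r) + 1, shape = "disc")
  bg <- 255 * as_img_matrix(EBImage::opening(px / 255, brush))
  px <- pmax(px - bg, 0)
  px <- EBImage::gblur(px, sigma = params$gaussian_sigma_px)
  px <- pmin(pmax(px, 0), 255)
  gray_image(as_img_matrix(px), pixel_size_um, "signal_bright")
}

# strip EBImage Image class back to a plain numeric matrix
as_img_matrix <- function(x) {
  x <- EBImage::imageData(x)
  if (length(dim(x)) > 2) x <- x[, , 1]
  matrix(as.numeric(x), nrow(x), ncol(x))
}

#' Seed and watershed thresholds
#'
#' `compute_seed_threshold()` returns `Th1 = I_max - f1 * I_SD`;
#' `compute_watershed_threshold()` returns `Th2 = I_mean + f2 * I_SD`. `I_max`,
#' `I_mean` and `I_SD` are the maximum, mean and standard deviation of the
#' pixel values of the (preprocessed) image.
#'
#' @param img `gray_image` or numeric matrix.
#' @param f1,f2 Dimensionless factors.
#' @return Threshold in gray units.
#' @export
compute_seed_threshold <- function(img, f1 = 2) {
  px <- img_pixels(img)
  if (length(px) == 0) abort("empty image")
  s <- sd(as.vector(px))
  if (is.na(s)) s <- 0
  max(px) - f1 * s
}

#' @rdname compute_seed_threshold
#' @export
compute_watershed_threshold <- function(img, f2 = 0.5) {
  px <- img_pixels(img)
  if (length(px) == 0) abort("empty image")
  s <- sd(as.vector(px))
  if (is.na(s)) s <- 0
  mean(px) + f2 * s
}

#' Detect soma seeds
#'
#' Seeds are the 8-connected components of pixels at or above Th1 whose area
#' is at least `seed_area_threshold_px`; each surviving component becomes one
#' seed label. An image with no qualifying component yields an empty seed map.
#'
#' @param img Preprocessed `signal_bright` image.
#' @param params [segmentation_params()].
#' @param th1 Seed threshold; computed from `img` and `params$f1` if missing.
#' @return A [label_map()] of seeds.
#' @export
detect_somata <- function(img, params = segmentation_params(), th1 = NULL) {
  px <- img_pixels(img)
  if (diff(range(px)) == 0) {
    # degenerate flat image: Th1 equals every pixel, there is no structure
    inform("image has no intensity variation; empty seed map")
    return(label_map(matrix(0L, nrow(px), ncol(px)), img_pixel_size(img)))
  }
  th1 <- th1 %||% compute_seed_threshold(img, params$f1)
  comps <- label8(px >= th1)
  if (max(comps) > 0) {
    areas <- tabulate(comps[comps > 0], nbins = max(comps))
    keep <- which(areas >= params$seed_area_threshold_px)
    comps[!(comps %in% keep)] <- 0L
    comps <- relabel_contiguous(comps)
    if (length(keep) == 0)
      inform("no soma seed passed the area threshold; empty seed map")
  }
  label_map(comps, img_pixel_size(img))
}

#' Seeded watershed restricted to supra-Th2 pixels
#'
#' Floods from the seed labels in order of decreasing intensity; only pixels
#' with intensity >= `th2` are assignable, ties are broken first-in-first-out,
#' and supra-threshold structures not connected to any seed stay background.
#'
#' @param img Preprocessed `signal_bright` image.
#' @param seeds [label_map()] of non-overlapping seeds.
#' @param th2 Watershed threshold, gray units.
#' @return A [label_map()]; every label is 8-connected and contains its seed.
#' @export
seeded_watershed <- function(img, seeds, th2) {
  px <- img_pixels(img)
  sd_ <- lab_pixels(seeds)
  if (!all(dim(px) == dim(sd_))) abort("image and seed map dimensions differ")
  out <- cpp_seeded_watershed(px, sd_, th2)
  label_map(out, img_pixel_size(img))
}

#' Remove cells at or below a minimum area
#'
#' Labels whose pixel count is less than or equal to `min_cell_area_px` are
#' dropped and the survivors relabeled contiguously.
#'
#' @param labels [label_map()] or integer matrix.
#' @param min_cell_area_px Area floor in pixels; survivors are strictly larger.
#' @return A [label_map()].
#' @export
filter_cells <- function(labels, min_cell_area_px = 900) {
  m <- lab_pixels(labels)
  if (max(m) > 0) {
    areas <- tabulate(m[m > 0], nbins = max(m))
    drop <- which(areas <= min_cell_area_px & areas > 0)
    m[m %in% drop] <- 0L
    m <- relabel_contiguous(m)
  }
  label_map(m, img_pixel_size(labels))
}

#' Run the full stained-section segmentation pipeline
#'
#' preprocess -> soma seed detection -> seeded watershed -> area filter ->
#' morphometrics.
#'
#' @param raw Raw image (matrix, RGB array or `gray_image`).
#' @param params [segmentation_params()].
#' @param pixel_size_um Calibration for bare matrix inputs.
#' @param polarity Polarity for bare matrix inputs.
#' @return A `glia_segmentation` object: list with `labels` ([label_map()]),
#'   `cells` (per-cell morphology tibble), `seeds`, `thresholds` and the
#'   preprocessed image.
#' @export
run_ihc_pipeline <- function(raw, params = segmentation_params(),
                             pixel_size_um = 1, polarity = "signal_dark") {
  img <- preprocess(raw, params, polarity = polarity, pixel_size_um = pixel_size_um)
  th1 <- compute_seed_threshold(img, params$f1)
  th2 <- compute_watershed_threshold(img, params$f2)
  seeds <- detect_somata(img, params, th1 = th1)
  ws <- seeded_watershed(img, seeds, th2)
  cells_map <- filter_cells(ws, params$min_cell_area_px)
  cells <- measure_cells(cells_map)
  structure(list(labels = cells_map, cells = cells, seeds = seeds,
                 thresholds = c(th1 = th1, th2 = th2), image = img,
                 params = params),
            class = "glia_segmentation")
}

#' @export
print.glia_segmentation <- function(x, ...) {
  cat(sprintf("<glia_segmentation> %d cells (Th1 = %.2f, Th2 = %.2f)\n",
              n_labels(x$labels), x$thresholds["th1"], x$thresholds["th2"]))
  invisible(x)
}

#' @export
tidy.glia_segmentation <- function(x, ...) x$cells

#' @export
glance.glia_segmentation <- function(x, ...) {
  tibble(n_cells = n_labels(x$labels), n_seeds = n_labels(x$seeds),
         th1 = unname(x$thresholds["th1"]), th2 = unname(x$thresholds["th2"]),
         mean_ramification_index = mean(x$cells$ramification_index),
         mean_area_px = mean(x$cells$area_px))
}
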