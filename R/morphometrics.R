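# Per-cell shape descriptors used throughout the morphology readouts:
# ramification index (1 - circularity), inscribed radius, Feret diameter,
# geodesic diameter, area, perimeter, centroid, plus grouped summaries.

# Crofton perimeter, 4 directions (horizontal, vertical, both diagonals).
# P = pi/4 * sum_theta n_theta * d_theta / 2, where n_theta is the number of
# fore/background transitions along all digital lines of that direction and
# d_theta their spacing (1 for axial, 1/sqrt(2) for diagonal families).
crofton_perimeter <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  padded <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  padded[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  n_h <- sum(abs(padded[, -1] - padded[, -ncol(padded)]))
  n_v <- sum(abs(padded[-1, ] - padded[-nrow(padded), ]))
  nr <- nrow(padded); nc <- ncol(padded)
  a <- padded[-nr, -nc]; b <- padded[-1, -1]    # down-right diagonal
  n_d1 <- sum(abs(a - b))
  a <- padded[-1, -nc]; b <- padded[-nr, -1]    # up-right diagonal
  n_d2 <- sum(abs(a - b))
  (pi / 4) * (n_h / 2 + n_v / 2 + (n_d1 + n_d2) * (1 / sqrt(2)) / 2)
}

# Maximum Feret diameter from the convex hull of pixel corner points.
feret_diameter <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NA_real_)
  # border pixels suffice for the hull
  on_border <- border_pixels(mask)
  idx <- which(on_border, arr.ind = TRUE)
  y <- idx[, 1]; x <- idx[, 2]
  pts <- cbind(x = c(x - 0.5, x - 0.5, x + 0.5, x + 0.5),
               y = c(y - 0.5, y + 0.5, y - 0.5, y + 0.5))
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  if (nrow(hp) == 1) return(sqrt(2))
  d2 <- outer(hp[, 1], hp[, 1], "-")^2 + outer(hp[, 2], hp[, 2], "-")^2
  sqrt(max(d2))
}

# Foreground pixels with at least one 8-neighbour outside the mask.
border_pixels <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- padded[2:(nr + 1L), 2:(nc + 1L)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    interior <- interior & padded[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  mask & !interior
}

#' Geodesic diameter of a connected mask
#'
#' Longest shortest path between any two pixels of the object without leaving
#' it, with Euclidean step weights (1 axial, sqrt(2) diagonal). Computed by
#' iterated farthest-point geodesic propagation started from the inner-most
#' pixel (maximum of the distance transform) and from the four bounding-box
#' extremities, iterating until the diameter stops growing.
#'
#' @param mask Logical matrix; must be a single 8-connected component.
#' @param connectivity Pixel connectivity; only 8 is supported.
#' @return Geodesic diameter in pixels.
#' @export
geodesic_diameter <- function(mask, connectivity = 8) {
  if (connectivity != 8) abort("only 8-connectivity is supported")
  mask <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  npix <- sum(mask)
  if (npix == 0) abort("empty mask")
  if (npix == 1) return(0)
  if (max(cpp_label8(mask)) != 1L) abort("mask must be a single connected component")
  idx <- which(mask)
  arr <- which(mask, arr.ind = TRUE)
  score <- list(
    idx[which.max(as.vector(EBImage::distmap(mask))[idx])],
    idx[which.min(arr[, 1] + arr[, 2])],
    idx[which.max(arr[, 1] + arr[, 2])],
    idx[which.min(arr[, 1] - arr[, 2])],
    idx[which.max(arr[, 1] - arr[, 2])])
  best <- 0
  for (s in unique(unlist(score))) {
    p <- s
    repeat {
      d <- cpp_geodesic_dist(mask, p)
      dmax <- max(d, na.rm = TRUE)
      if (dmax > best + 1e-9) {
        best <- dmax
        p <- which(d == dmax)[1]
      } else break
    }
  }
  best
}

#' Measure morphology of every cell in a label map
#'
#' All descriptors are computed on the binary mask of each label: area,
#' Crofton perimeter, circularity (`4 * pi * area / perimeter^2`, clipped to
#' 1), ramification index (`1 - circularity`), inscribed radius (maximum of
#' the Euclidean distance transform), maximum Feret diameter (convex hull of
#' pixel corners) and geodesic diameter. Values are reported in pixels and,
#' using the pixel calibration, in micrometers.
#'
#' @param labels A [label_map()] or integer matrix.
#' @param pixel_size_um Calibration; defaults to the label map's.
#' @param fill_holes Fill interior holes before measuring perimeter-derived
#'   descriptors (staining gaps should not inflate the perimeter).
#' @return A tibble with one row per cell.
#' @export
measure_cells <- function(labels, pixel_size_um = NULL, fill_holes = TRUE) {
  px <- pixel_size_um %||% img_pixel_size(labels)
  m <- lab_pixels(labels)
  ids <- sort(setdiff(unique(as.vector(m)), 0L))
  rows <- lapply(ids, function(id) measure_cell_mask(m == id, id, px, fill_holes))
  if (length(rows) == 0) {
    return(tibble(label = integer(), area_px = numeric(), area_um2 = numeric(),
                  perimeter_px = numeric(), perimeter_um = numeric(),
                  circularity = numeric(), ramification_index = numeric(),
                  inscribed_radius_px = numeric(), inscribed_radius_um = numeric(),
                  feret_diameter_px = numeric(), feret_diameter_um = numeric(),
                  geodesic_diameter_px = numeric(), geodesic_diameter_um = numeric(),
                  centroid_x = numeric(), centroid_y = numeric()))
  }
  dplyr::bind_rows(rows)
}

#' @rdname measure_cells
#' @param label Single label id to measure.
#' @export
measure_cell <- function(labels, label, pixel_size_um = NULL, fill_holes = TRUE) {
  px <- pixel_size_um %||% img_pixel_size(labels)
  m <- lab_pixels(labels)
  if (!any(m == label)) abort(sprintf("label %s not present in label map", label))
  measure_cell_mask(m == label, label, px, fill_holes)
}

measure_cell_mask <- function(mask, id, px, fill_holes) {
  area <- sum(mask)
  meas_mask <- if (fill_holes) EBImage::fillHull(mask) > 0 else mask
  perim <- crofton_perimeter(meas_mask)
  circ <- if (perim > 0) min(1, 4 * pi * sum(meas_mask) / perim^2) else 1
  insc <- max(EBImage::distmap(meas_mask))
  fer <- feret_diameter(mask)
  geo <- geodesic_diameter(mask)
  idx <- which(mask, arr.ind = TRUE)
  tibble(label = as.integer(id),
         area_px = area, area_um2 = area * px^2,
         perimeter_px = perim, perimeter_um = perim * px,
         circularity = circ, ramification_index = 1 - circ,
         inscribed_radius_px = insc, inscribed_radius_um = insc * px,
         feret_diameter_px = fer, feret_diameter_um = fer * px,
         geodesic_diameter_px = geo, geodesic_diameter_um = geo * px,
         centroid_x = mean(idx[, 2]), centroid_y = mean(idx[, 1]))
}

#' Cell density per square millimetre
#'
#' @param labels A [label_map()] or integer matrix.
#' @param roi_area_mm2 Area of the analyzed region in mm^2 (> 0).
#' @return Cells per mm^2.
#' @export
cell_density <- function(labels, roi_area_mm2) {
  if (!is.numeric(roi_area_mm2) || roi_area_mm2 <= 0)
    abort("`roi_area_mm2` must be positive")
  n_labels(labels) / roi_area_mm2
}

#' Hierarchical group means of per-cell morphology
#'
#' Cell-level metrics are averaged per section first, then section means are
#' averaged per animal (so unequal cell counts between sections do not weight
#' the animal mean), one output row per animal (and region, if present).
#'
#' @param cells Data frame of per-cell records carrying grouping keys.
#' @param metrics Character vector of metric columns; defaults to all numeric
#'   columns that are not grouping keys.
#' @param animal,section,region Names of the grouping columns (region
#'   optional: used when present in `cells`).
#' @return A tibble with one row per animal (x region).
#' @export
aggregate_by_group <- function(cells, metrics = NULL,
                               animal = "animal", section = "section",
                               region = "region") {
  cells <- as_tibble(cells)
  for (key in c(animal, section))
    if (!key %in% names(cells)) abort(sprintf("missing grouping column '%s'", key))
  keys <- c(animal, if (region %in% names(cells)) region)
  if (is.null(metrics)) {
    metrics <- names(cells)[vapply(cells, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c(animal, section, region, "label"))
  }
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(keys, section)))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(n_sections = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics), mean), .groups = "drop")
}
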