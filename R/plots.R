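# ggplot2 visualisations for each result type.

image_to_df <- function(px) {
  tibble(x = rep(seq_len(ncol(px)), each = nrow(px)),
         y = rep(seq_len(nrow(px)), times = ncol(px)),
         intensity = as.vector(px))
}

#' Plot a grayscale image
#'
#' @param object A [gray_image()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gray_image <- function(object, ...) {
  df <- image_to_df(object$pixels)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = "gray")
}

#' Plot a segmentation result as an overlay
#'
#' Preprocessed image with cell outlines and labels.
#'
#' @param object A `glia_segmentation` from [run_ihc_pipeline()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glia_segmentation <- function(object, ...) {
  df <- image_to_df(object$image$pixels)
  lab <- lab_pixels(object$labels)
  edge <- border_pixels(lab > 0)
  idx <- which(edge, arr.ind = TRUE)
  outline <- tibble(x = idx[, 2], y = idx[, 1],
                    label = factor(lab[idx]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (nrow(outline) > 0)
    p <- p + ggplot2::geom_point(data = outline, size = 0.1,
                                 ggplot2::aes(colour = .data$label), show.legend = FALSE)
  if (nrow(object$cells) > 0)
    p <- p + ggplot2::geom_text(data = object$cells, colour = "yellow", size = 3,
                                ggplot2::aes(x = .data$centroid_x, y = .data$centroid_y,
                                             label = .data$label))
  p
}

#' Plot comet tracks
#'
#' Kept tracks drawn over all spot detections, colored by direction when
#' available.
#'
#' @param object A `comet_tracks` from [track_comets()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.comet_tracks <- function(object, ...) {
  spots <- object$spots
  kept_ids <- object$kept$track
  kept_spots <- spots[spots$track %in% kept_ids, , drop = FALSE]
  if ("direction" %in% names(object$kept))
    kept_spots <- dplyr::left_join(kept_spots,
                                   object$kept[, c("track", "direction")], by = "track")
  else kept_spots$direction <- "track"
  p <- ggplot2::ggplot(spots, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.3, colour = "grey60") +
    ggplot2::geom_path(data = kept_spots,
                       ggplot2::aes(group = .data$track, colour = .data$direction)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = NULL)
  if (!is.null(object$centrosome_xy_um))
    p <- p + ggplot2::annotate("point", x = object$centrosome_xy_um[1],
                               y = object$centrosome_xy_um[2], shape = 3, size = 3)
  p
}

#' Plot a radial profile
#'
#' Per-ring integrated density with the cumulative fraction and the radius at
#' 80% cumulative density.
#'
#' @param object A [radial_profile()].
#' @param fraction Fraction whose radius is marked (default 0.8).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.radial_profile <- function(object, fraction = 0.8, ...) {
  r <- tryCatch(as.numeric(radius_at_fraction(object, fraction)),
                error = function(e) NA_real_)
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$r_inner + 0.5)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$integrated_density), width = 1,
                      fill = "grey70") +
    ggplot2::geom_line(ggplot2::aes(
      y = .data$cumulative_fraction * max(.data$integrated_density)), colour = "red") +
    ggplot2::labs(x = "radius (px)", y = "integrated density")
  if (is.finite(r))
    p <- p + ggplot2::geom_vline(xintercept = r, linetype = 2)
  p
}

#' Compare morphology between groups
#'
#' Violin + point summary of a per-cell metric across groups.
#'
#' @param cells Per-cell tibble with a grouping column.
#' @param metric Metric column name (default `ramification_index`).
#' @param group Grouping column name.
#' @return A ggplot.
#' @export
plot_morphology <- function(cells, metric = "ramification_index",
                            group = "morphology_class") {
  ggplot2::ggplot(cells, ggplot2::aes(.data[[group]], .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.1, size = 0.8, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = metric)
}
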