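# Hierarchical-watershed segmentation of CellMask-stained cultured microglia:
# seeds are regional maxima surviving a fixed dynamics h, cells are grown by
# seeded watershed above 10x the per-image minimum intensity, small objects
# dropped, and morphology aggregated per well relative to untreated wells.

#' Parameters for in-vitro (culture) segmentation
#'
#' @param seed_dynamics_h Seed dynamics threshold in gray units, default 10000
#'   on the native 16-bit scale (rescale for 8-bit inputs).
#' @param min_area_px Minimum cell area in pixels (default 200); smaller
#'   labels are removed.
#' @param threshold_factor The intensity floor is `threshold_factor` times the
#'   per-image minimum intensity (default 10).
#' @param object_splitting Secondary shape-based splitting of merged objects;
#'   off by default and not implemented (each surviving seed yields exactly
#'   one region).
#' @return An `invitro_params` list.
#' @export
invitro_params <- function(seed_dynamics_h = 10000, min_area_px = 200,
                           threshold_factor = 10, object_splitting = FALSE) {
  if (seed_dynamics_h <= 0) abort("`seed_dynamics_h` must be positive")
  if (threshold_factor < 1) abort("`threshold_factor` must be at least 1")
  if (isTRUE(object_splitting)) abort("object splitting is not implemented")
  structure(list(seed_dynamics_h = seed_dynamics_h, min_area_px = min_area_px,
                 threshold_factor = threshold_factor,
                 object_splitting = FALSE),
            class = "invitro_params")
}

#' Seeds from regional maxima with dynamics at least h
#'
#' The dynamics of a regional maximum is the minimal intensity drop separating
#' it from a higher maximum along the best path; maxima with dynamics below
#' `h` are suppressed (merged into their higher neighbor). Each surviving
#' maximum contributes its plateau as one seed. A flat image has no maxima and
#' yields an empty seed map.
#'
#' @param img `gray_image` or numeric matrix, signal-bright.
#' @param h Dynamics threshold, gray units.
#' @return A [label_map()] of seeds.
#' @export
h_maxima_seeds <- function(img, h) {
  px <- img_pixels(img)
  seeds <- matrix(0L, nrow(px), ncol(px))
  if (diff(range(px)) > 0) {
    dyn <- cpp_dynamics(px)
    keep <- which(dyn$dynamics >= h)
    for (k in seq_along(keep))
      seeds[dyn$plateau[[keep[k]]]] <- k
  }
  label_map(seeds, img_pixel_size(img))
}

#' Segment cultured cells by hierarchical watershed
#'
#' Seeded watershed from h-maxima seeds, restricted to pixels at or above
#' `threshold_factor` times the per-image minimum intensity; labels smaller
#' than `min_area_px` are removed and survivors relabeled.
#'
#' @param img `gray_image` or numeric matrix, signal-bright.
#' @param params [invitro_params()].
#' @return A [label_map()].
#' @export
segment_invitro <- function(img, params = invitro_params()) {
  px <- img_pixels(img)
  mn <- min(px)
  if (mn == 0)
    warn("per-image minimum intensity is 0; watershed threshold is 0")
  th <- params$threshold_factor * mn
  seeds <- h_maxima_seeds(img, params$seed_dynamics_h)
  ws <- cpp_seeded_watershed(px, lab_pixels(seeds), th)
  # drop seeds whose plateau lies below the intensity floor
  ws[px < th] <- 0L
  if (max(ws) > 0) {
    areas <- tabulate(ws[ws > 0], nbins = max(ws))
    drop <- which(areas < params$min_area_px & areas > 0)
    ws[ws %in% drop] <- 0L
    ws <- relabel_contiguous(ws)
  }
  label_map(ws, img_pixel_size(img))
}

#' Aggregate per-cell morphology per well, relative to a reference group
#'
#' Cells from all fields of view of a well are pooled and averaged, then each
#' well value is divided by the mean over the wells of the reference
#' (untreated) group. Wells with no cells are flagged and excluded from group
#' means.
#'
#' @param cells Data frame of per-cell records with `well` and `group`
#'   columns (one row per cell, any number of fields of view per well).
#' @param reference_group Value of `group` used for normalization.
#' @param metrics Metric columns to aggregate; default all numeric columns
#'   except identifiers.
#' @param well_map Optional data frame with `well` and `group` columns listing
#'   every imaged well; wells without any cell are then reported with
#'   `n_cells = 0`, flagged `empty` and excluded from group means.
#' @return A tibble with one row per well: `n_cells`, absolute means and
#'   `rel_*` columns relative to the reference-group mean.
#' @export
aggregate_per_well <- function(cells, reference_group, metrics = NULL,
                               well_map = NULL) {
  cells <- as_tibble(cells)
  for (key in c("well", "group"))
    if (!key %in% names(cells)) abort(sprintf("missing column '%s'", key))
  if (is.null(metrics)) {
    metrics <- names(cells)[vapply(cells, is.numeric, logical(1))]
    metrics <- setdiff(metrics, c("label", "well", "group", "fov"))
  }
  wells <- cells |>
    dplyr::group_by(.data$group, .data$well) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     dplyr::across(dplyr::all_of(metrics), mean),
                     .groups = "drop")
  if (!is.null(well_map)) {
    well_map <- dplyr::distinct(as_tibble(well_map)[, c("well", "group")])
    wells <- dplyr::left_join(well_map, wells, by = c("well", "group"))
    wells$n_cells[is.na(wells$n_cells)] <- 0L
  }
  wells <- dplyr::mutate(wells, empty = .data$n_cells == 0)
  if (!reference_group %in% wells$group)
    abort(sprintf("reference group '%s' not present", reference_group))
  ref <- wells |>
    dplyr::filter(.data$group == reference_group, !.data$empty) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metrics), mean))
  if (nrow(ref) == 0 || any(!is.finite(unlist(ref))))
    abort("reference group has no usable wells")
  for (m in metrics)
    wells[[paste0("rel_", m)]] <- wells[[m]] / ref[[m]]
  wells
}
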