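# End-to-end orchestration: a single YAML config with per-stage blocks drives
# simulation, segmentation, morphometry, tracking and spatial statistics, with
# a provenance manifest and deterministic outputs for a given config + seed.

#' Run the pipeline from a configuration
#'
#' The config is a YAML file (or an equivalent named list) with top-level
#' fields `stages` (any of `"simulate"`, `"segment_ihc"`, `"segment_invitro"`,
#' `"track_comets"`, `"radial_stats"`), `out_dir`, `rng_seed`, optional input
#' paths per stage and per-stage parameter blocks (`phantom`, `segmentation`,
#' `invitro`, `comets`, `tracking`, `radial`). Outputs (CSV tables, label
#' TIFFs) and a `manifest.json` recording the package version, a config hash
#' and per-stage counts are written to `out_dir`. A failing stage leaves a
#' `FAILED` marker next to the partial outputs.
#'
#' @param config Path to a YAML file or a named list.
#' @param out_dir Output directory; overrides the config's.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) abort(sprintf("config file '%s' does not exist", config))
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% abort("`out_dir` is required")
  stages <- config$stages %||% "simulate"
  # validate referenced inputs before any processing
  for (f in c(config$segment_ihc$image, config$segment_invitro$image,
              config$track_comets$stack))
    if (!is.null(f) && !file.exists(f))
      abort(sprintf("input file '%s' does not exist", f))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$rng_seed %||% 1L
  manifest <- list(package = "gliascope",
                   version = as.character(utils::packageVersion("gliascope")),
                   config_hash = rlang::hash(config),
                   rng_seed = seed, stages = list())
  sim <- NULL
  on_fail <- function(stage, e) {
    writeLines(c(stage, conditionMessage(e)), file.path(out_dir, "FAILED"))
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  for (stage in stages) {
    res <- tryCatch(switch(
      stage,
      simulate = {
        pp <- do.call(phantom_params, c(config$phantom %||% list(),
                                        list(rng_seed = seed)))
        sim <- generate_microglia_phantom(pp)
        write_table(sim$cells, file.path(out_dir, "phantom_true_cells.csv"))
        write_gray_tiff(sim$image, file.path(out_dir, "phantom.tif"))
        write_gray_tiff(lab_pixels(sim$labels) / max(1, max(lab_pixels(sim$labels))) * 255,
                        file.path(out_dir, "phantom_truth_labels.tif"))
        list(n_cells = n_labels(sim$labels))
      },
      segment_ihc = {
        sp <- do.call(segmentation_params, config$segmentation %||% list())
        img <- if (!is.null(config$segment_ihc$image))
          read_gray_tiff(config$segment_ihc$image,
                         pixel_size_um = config$pixel_size_um %||% 1,
                         polarity = config$segment_ihc$polarity %||% "signal_dark")
        else if (!is.null(sim)) sim$image
        else abort("segment_ihc needs an input image or a simulate stage")
        seg <- run_ihc_pipeline(img, sp)
        write_table(seg$cells, file.path(out_dir, "cells.csv"))
        write_gray_tiff(lab_pixels(seg$labels) / max(1, max(lab_pixels(seg$labels))) * 255,
                        file.path(out_dir, "labels.tif"))
        list(n_cells = n_labels(seg$labels), th1 = unname(seg$thresholds["th1"]),
             th2 = unname(seg$thresholds["th2"]))
      },
      segment_invitro = {
        ip <- do.call(invitro_params, config$invitro %||% list())
        img <- if (!is.null(config$segment_invitro$image))
          read_gray_tiff(config$segment_invitro$image,
                         pixel_size_um = config$pixel_size_um %||% 1)
        else if (!is.null(sim)) sim$image
        else abort("segment_invitro needs an input image or a simulate stage")
        labs <- segment_invitro(img, ip)
        cells <- measure_cells(labs)
        write_table(cells, file.path(out_dir, "invitro_cells.csv"))
        list(n_cells = n_labels(labs))
      },
      track_comets = {
        tp <- do.call(tracking_params, config$tracking %||% list())
        cp <- do.call(comet_movie_params, c(config$comets %||% list(),
                                            list(rng_seed = seed)))
        if (!is.null(config$track_comets$stack)) {
          frames <- read_stack_tiff(config$track_comets$stack)
          centro <- config$track_comets$centrosome_xy_um
        } else {
          mv <- generate_comet_movie(cp)
          frames <- mv$frames
          centro <- (cp$centrosome_xy - 1) * cp$pixel_size_um
          write_table(mv$tracks, file.path(out_dir, "true_tracks.csv"))
        }
        tk <- track_comets(frames, tp, pixel_size_um = cp$pixel_size_um,
                           centrosome_xy_um = centro)
        write_table(tk$kept, file.path(out_dir, "tracks.csv"))
        write_table(tk$summary, file.path(out_dir, "track_summary.csv"))
        list(n_tracks = nrow(tk$kept),
             fraction_outward = tk$summary$fraction_outward)
      },
      radial_stats = {
        rc <- config$radial %||% list()
        img <- if (!is.null(rc$image)) read_gray_tiff(rc$image)
        else do.call(generate_radial_intensity_image,
                     c(rc[intersect(names(rc), names(formals(generate_radial_intensity_image)))],
                       list(seed = seed)))
        ctr <- rc$center %||% attr_center(img)
        prof <- radial_profile(img, ctr)
        r80 <- radius_at_fraction(prof, rc$fraction %||% 0.8)
        write_table(as_tibble(prof), file.path(out_dir, "radial_profile.csv"))
        list(r80_px = as.numeric(r80))
      },
      abort(sprintf("unknown stage '%s'", stage))),
      error = function(e) on_fail(stage, e))
    manifest$stages[[stage]] <- res
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

attr_center <- function(img) {
  px <- img_pixels(img)
  c(ncol(px) / 2, nrow(px) / 2)
}

# Output tables are written with numerics rounded to 12 significant digits:
# that precision survives CSV parsing exactly, so written tables round-trip
# (write -> read -> write) byte-identically.
write_table <- function(x, path) {
  num <- vapply(x, function(col) is.double(col), logical(1))
  x[num] <- lapply(x[num], signif, digits = 12)
  readr::write_csv(x, path)
}
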