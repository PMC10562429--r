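# Microtubule plus-tip comet analysis: LoG spot detection at sub-pixel
# resolution, LAP frame-to-frame linking with gap closing (no merge/split),
# track filtering by length and confinement, and outward/inward
# classification relative to the centrosome.

#' Tracking parameters
#'
#' Defaults follow the plus-tip tracking configuration: LoG detection at
#' 0.4 um radius, maximum linking distance 1.5 um, gap closing up to 0.5 um
#' over at most 4 frames, tracks kept with >= 4 spots and confinement ratio
#' >= 0.8. The detection threshold is in raw (scale-normalized) LoG response
#' units and is tuned per movie to the expression level.
#'
#' @param log_radius_um Comet radius for the LoG filter, micrometers.
#' @param detection_threshold Minimum LoG response of a detected spot.
#' @param max_link_um Maximum frame-to-frame linking distance, micrometers.
#' @param gap_close_um Maximum gap-closing distance, micrometers.
#' @param max_frame_gap Maximum frame gap bridged when closing gaps.
#' @param min_spots Minimum spots per retained track.
#' @param min_confinement Minimum confinement ratio (net displacement over
#'   path length) of retained tracks.
#' @param frame_interval_s Time between frames, seconds.
#' @return A `tracking_params` list.
#' @export
tracking_params <- function(log_radius_um = 0.4, detection_threshold = 1.4,
                            max_link_um = 1.5, gap_close_um = 0.5,
                            max_frame_gap = 4, min_spots = 4,
                            min_confinement = 0.8, frame_interval_s = 1) {
  p <- list(log_radius_um = log_radius_um, detection_threshold = detection_threshold,
            max_link_um = max_link_um, gap_close_um = gap_close_um,
            max_frame_gap = as.integer(max_frame_gap), min_spots = as.integer(min_spots),
            min_confinement = min_confinement, frame_interval_s = frame_interval_s)
  if (any(unlist(p[c(1, 3, 4, 5, 6, 8)]) <= 0)) abort("tracking parameters must be positive")
  if (min_confinement < 0 || min_confinement > 1)
    abort("`min_confinement` must lie in [0, 1]")
  structure(p, class = "tracking_params")
}

# LoG kernel, zero-mean and amplitude-calibrated: a Gaussian spot of matched
# sigma and peak amplitude A yields a response of A, so detection thresholds
# are in gray units of spot amplitude.
log_kernel <- function(sigma_px) {
  ext <- max(2L, ceiling(3 * sigma_px))
  xs <- -ext:ext
  r2 <- outer(xs^2, xs^2, "+")
  k <- -(r2 - 2 * sigma_px^2) / sigma_px^2 * exp(-r2 / (2 * sigma_px^2))
  k <- k - mean(k)
  k / sum(k * exp(-r2 / (2 * sigma_px^2)))
}

# Convolution with replicate padding (avoids FFT wrap-around at the borders).
conv_replicate <- function(img, kernel) {
  ext <- (nrow(kernel) - 1L) / 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, ext), seq_len(nr), rep(nr, ext))
  ci <- c(rep(1L, ext), seq_len(nc), rep(nc, ext))
  padded <- img[ri, ci]
  out <- EBImage::filter2(padded, kernel, boundary = "circular")
  as_img_matrix(out)[(ext + 1):(ext + nr), (ext + 1):(ext + nc)]
}

#' Detect comet spots in one frame
#'
#' Laplacian-of-Gaussian filtering at the scale matching `log_radius_um`
#' (sigma = radius / sqrt(2)), 8-neighborhood local maxima above the detection
#' threshold, and sub-pixel refinement by a quadratic fit of the response in
#' the 3x3 neighborhood.
#'
#' @param frame Numeric matrix or `gray_image`, single channel.
#' @param params [tracking_params()].
#' @param pixel_size_um Calibration, micrometers per pixel.
#' @param frame_index Frame number recorded in the output.
#' @return Tibble with `frame`, `x_px`, `y_px`, `x_um`, `y_um`, `intensity`,
#'   `quality` (LoG response).
#' @export
detect_spots <- function(frame, params = tracking_params(), pixel_size_um = 0.11,
                         frame_index = 1L) {
  px <- img_pixels(frame)
  pixel_size_um <- if (inherits(frame, "gray_image")) frame$pixel_size_um else pixel_size_um
  radius_px <- params$log_radius_um / pixel_size_um
  if (radius_px < 1)
    abort("LoG radius is below 1 px at this calibration; check `pixel_size_um`")
  sigma <- radius_px / sqrt(2)
  resp <- conv_replicate(px, log_kernel(sigma))
  nr <- nrow(resp); nc <- ncol(resp)
  if (nr < 3 || nc < 3) return(empty_spots())
  ctr <- resp[2:(nr - 1), 2:(nc - 1)]
  is_max <- ctr >= params$detection_threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (ctr > resp[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc)])
  }
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty_spots())
  y <- hits[, 1] + 1L; x <- hits[, 2] + 1L
  # sub-pixel refinement: quadratic fit seeded, then iterated Gaussian-weighted
  # centroid of the positive response around the peak (lower RMSE than the
  # 3-point parabola alone at low SNR)
  off1d <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    off <- ifelse(abs(den) > .Machine$double.eps, (rm - rp) / (2 * den), 0)
    pmin(pmax(off, -0.5), 0.5)
  }
  ox <- off1d(resp[cbind(y, x - 1L)], resp[cbind(y, x)], resp[cbind(y, x + 1L)])
  oy <- off1d(resp[cbind(y - 1L, x)], resp[cbind(y, x)], resp[cbind(y + 1L, x)])
  win <- max(2L, ceiling(1.5 * sigma))
  xs_ref <- x + ox; ys_ref <- y + oy
  for (k in seq_along(xs_ref)) {
    cx <- xs_ref[k]; cy <- ys_ref[k]
    for (it in 1:2) {
      rr <- max(1L, round(cy) - win):min(nr, round(cy) + win)
      cc <- max(1L, round(cx) - win):min(nc, round(cx) + win)
      wts <- exp(-outer((rr - cy)^2, (cc - cx)^2, "+") / (2 * sigma^2)) *
        pmax(resp[rr, cc, drop = FALSE], 0)
      sw <- sum(wts)
      if (sw <= 0) break
      cy2 <- sum(rr * rowSums(wts)) / sw
      cx2 <- sum(cc * colSums(wts)) / sw
      # never drift beyond the detection pixel
      cy <- min(max(cy2, y[k] - 1), y[k] + 1)
      cx <- min(max(cx2, x[k] - 1), x[k] + 1)
    }
    xs_ref[k] <- cx; ys_ref[k] <- cy
  }
  tibble(frame = as.integer(frame_index),
         x_px = xs_ref, y_px = ys_ref,
         x_um = (xs_ref - 1) * pixel_size_um, y_um = (ys_ref - 1) * pixel_size_um,
         intensity = px[cbind(y, x)], quality = resp[cbind(y, x)])
}

empty_spots <- function() {
  tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
         x_um = numeric(), y_um = numeric(), intensity = numeric(),
         quality = numeric())
}

#' @rdname detect_spots
#' @param frames List of matrices (a movie).
#' @export
detect_spots_stack <- function(frames, params = tracking_params(), pixel_size_um = 0.11) {
  dplyr::bind_rows(lapply(seq_along(frames), function(t)
    detect_spots(frames[[t]], params, pixel_size_um, frame_index = t)))
}

# Maximum-cardinality, minimum total squared distance partial matching between
# two point sets, restricted to pairs within max_dist. Returns for each row
# point the matched column index or NA.
match_frame_pair <- function(a, b, max_dist) {
  n1 <- nrow(a); n2 <- nrow(b)
  if (n1 == 0 || n2 == 0) return(rep(NA_integer_, n1))
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  allowed <- d2 <= max_dist^2
  if (!any(allowed)) return(rep(NA_integer_, n1))
  FORBID <- 1e9
  B <- 1e5  # dummy (non-link) cost; >> any total allowed d2
  n <- n1 + n2
  cost <- matrix(0, n, n)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(allowed, d2, FORBID)
  cost[seq_len(n1), (n2 + 1):n] <- FORBID
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- B
  cost[(n1 + 1):n, seq_len(n2)] <- FORBID
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- B
  asg <- cpp_lap(cost)
  out <- asg[seq_len(n1)]
  out[out > n2] <- NA_integer_
  # safety: never accept a forbidden pairing
  sel <- which(!is.na(out))
  if (length(sel) > 0) {
    bad <- !allowed[cbind(sel, out[sel])]
    out[sel[bad]] <- NA_integer_
  }
  out
}

#' Link detected spots into tracks
#'
#' Frame-to-frame linking by optimal one-to-one assignment minimizing total
#' distance among pairs within `max_link_um` (maximum-cardinality bipartite
#' matching with a non-link option), followed by gap closing: track ends are
#' joined to later track starts within `gap_close_um` and at most
#' `max_frame_gap` frames, greedily by ascending distance. No merging or
#' splitting.
#'
#' @param spots Tibble from [detect_spots_stack()] (needs `frame`, `x_um`,
#'   `y_um`).
#' @param params [tracking_params()].
#' @return The `spots` tibble with a `track` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(spots, params = tracking_params()) {
  spots <- dplyr::arrange(as_tibble(spots), .data$frame)
  n <- nrow(spots)
  if (n == 0) return(dplyr::mutate(spots, track = integer()))
  track <- integer(n)
  next_track <- 0L
  frames <- sort(unique(spots$frame))
  idx_by_frame <- split(seq_len(n), spots$frame)
  prev_idx <- integer(0)
  for (fi in seq_along(frames)) {
    cur_idx <- idx_by_frame[[as.character(frames[fi])]]
    matched_cur <- rep(NA_integer_, length(cur_idx))
    if (length(prev_idx) > 0 && fi > 1 && frames[fi] == frames[fi - 1] + 1L) {
      a <- cbind(spots$x_um[prev_idx], spots$y_um[prev_idx])
      b <- cbind(spots$x_um[cur_idx], spots$y_um[cur_idx])
      m <- match_frame_pair(a, b, params$max_link_um)
      for (i in seq_along(m))
        if (!is.na(m[i])) {
          track[cur_idx[m[i]]] <- track[prev_idx[i]]
          matched_cur[m[i]] <- i
        }
    }
    for (j in which(is.na(matched_cur))) {
      next_track <- next_track + 1L
      track[cur_idx[j]] <- next_track
    }
    prev_idx <- cur_idx
  }
  spots$track <- track
  spots <- close_gaps(spots, params)
  dplyr::arrange(spots, .data$track, .data$frame)
}

# Greedy gap closing by ascending end-to-start distance.
close_gaps <- function(spots, params) {
  ends <- spots |>
    dplyr::group_by(.data$track) |>
    dplyr::slice_max(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  starts <- spots |>
    dplyr::group_by(.data$track) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  cand <- tidyr::expand_grid(e = seq_len(nrow(ends)), s = seq_len(nrow(starts)))
  gap <- starts$frame[cand$s] - ends$frame[cand$e]
  d <- sqrt((starts$x_um[cand$s] - ends$x_um[cand$e])^2 +
              (starts$y_um[cand$s] - ends$y_um[cand$e])^2)
  ok <- gap >= 1 & gap <= params$max_frame_gap & d <= params$gap_close_um &
    ends$track[cand$e] != starts$track[cand$s]
  cand <- cand[ok, , drop = FALSE]
  d <- d[ok]
  ord <- order(d)
  end_used <- logical(nrow(ends)); start_used <- logical(nrow(starts))
  remap <- seq_len(max(spots$track, 0L))
  resolve <- function(t) { while (remap[t] != t) t <- remap[t]; t }
  for (k in ord) {
    e <- cand$e[k]; s <- cand$s[k]
    if (end_used[e] || start_used[s]) next
    te <- resolve(ends$track[e]); ts <- resolve(starts$track[s])
    if (te == ts) next
    remap[ts] <- te
    end_used[e] <- TRUE; start_used[s] <- TRUE
  }
  spots$track <- vapply(spots$track, resolve, integer(1))
  spots$track <- as.integer(factor(spots$track, levels = unique(spots$track)))
  spots
}

#' Per-track metrics
#'
#' @param spots Linked spots tibble (with `track`).
#' @param params [tracking_params()] (for the frame interval).
#' @return Tibble with one row per track: `n_spots`, `path_length_um`,
#'   `net_displacement_um`, `confinement_ratio`, `mean_speed_um_s`, first/last
#'   positions and frames.
#' @export
track_metrics <- function(spots, params = tracking_params()) {
  spots |>
    dplyr::arrange(.data$track, .data$frame) |>
    dplyr::group_by(.data$track) |>
    dplyr::summarise(
      n_spots = dplyr::n(),
      first_frame = dplyr::first(.data$frame), last_frame = dplyr::last(.data$frame),
      x0_um = dplyr::first(.data$x_um), y0_um = dplyr::first(.data$y_um),
      xn_um = dplyr::last(.data$x_um), yn_um = dplyr::last(.data$y_um),
      path_length_um = sum(sqrt(diff(.data$x_um)^2 + diff(.data$y_um)^2)),
      .groups = "drop") |>
    dplyr::mutate(
      net_displacement_um = sqrt((.data$xn_um - .data$x0_um)^2 +
                                   (.data$yn_um - .data$y0_um)^2),
      confinement_ratio = ifelse(.data$path_length_um > 0,
                                 pmin(1, .data$net_displacement_um / .data$path_length_um), 1),
      mean_speed_um_s = ifelse(.data$last_frame > .data$first_frame,
                               .data$path_length_um /
                                 ((.data$last_frame - .data$first_frame) * params$frame_interval_s),
                               NA_real_))
}

#' Filter tracks by length and confinement
#'
#' Keeps tracks with at least `min_spots` spots and confinement ratio at
#' least `min_confinement`, excluding short and non-linear tracks.
#'
#' @param tracks Per-track tibble from [track_metrics()].
#' @param params [tracking_params()].
#' @return Filtered per-track tibble.
#' @export
filter_tracks <- function(tracks, params = tracking_params()) {
  dplyr::filter(tracks, .data$n_spots >= params$min_spots,
                .data$confinement_ratio >= params$min_confinement)
}

#' Classify track direction relative to the centrosome
#'
#' A track is outward when its last spot is strictly farther from the
#' centrosome than its first spot (`dn > d0`); otherwise (including exact
#' ties) inward.
#'
#' @param tracks Per-track tibble from [track_metrics()].
#' @param centrosome_xy Centrosome position `c(x, y)` in micrometers.
#' @return `tracks` with `d0_um`, `dn_um` and `direction` columns.
#' @export
classify_direction <- function(tracks, centrosome_xy) {
  if (missing(centrosome_xy) || is.null(centrosome_xy) || length(centrosome_xy) != 2)
    abort("`centrosome_xy` (x, y in micrometers) is required")
  tracks |>
    dplyr::mutate(
      d0_um = sqrt((.data$x0_um - centrosome_xy[1])^2 + (.data$y0_um - centrosome_xy[2])^2),
      dn_um = sqrt((.data$xn_um - centrosome_xy[1])^2 + (.data$yn_um - centrosome_xy[2])^2),
      direction = ifelse(.data$dn_um > .data$d0_um, "outward", "inward"))
}

#' Summarize tracks per cell
#'
#' @param tracks Filtered, direction-classified per-track tibble.
#' @param centrosome_xy Centrosome position, micrometers; used to classify
#'   direction if `tracks` has no `direction` column.
#' @param params [tracking_params()].
#' @return One-row tibble: `n_tracks`, `mean_speed_um_s`,
#'   `mean_displacement_um` (net), `mean_path_length_um`, `fraction_outward`.
#' @export
summarize_cell <- function(tracks, centrosome_xy = NULL, params = tracking_params()) {
  if (!"direction" %in% names(tracks)) {
    tracks <- classify_direction(tracks, centrosome_xy)
  }
  if (nrow(tracks) == 0) {
    return(tibble(n_tracks = 0L, mean_speed_um_s = NA_real_,
                  mean_displacement_um = NA_real_, mean_path_length_um = NA_real_,
                  fraction_outward = NA_real_))
  }
  tibble(n_tracks = nrow(tracks),
         mean_speed_um_s = mean(tracks$mean_speed_um_s, na.rm = TRUE),
         mean_displacement_um = mean(tracks$net_displacement_um),
         mean_path_length_um = mean(tracks$path_length_um),
         fraction_outward = mean(tracks$direction == "outward"))
}

#' Track comets in a movie, end to end
#'
#' Detection, linking, metric computation, filtering, direction
#' classification and per-cell summary.
#'
#' @param frames List of matrices (one per frame).
#' @param params [tracking_params()].
#' @param pixel_size_um Calibration, micrometers per pixel.
#' @param centrosome_xy_um Centrosome position `c(x, y)` in micrometers
#'   (located manually on the movie, or see [estimate_centrosome()]).
#' @return A `comet_tracks` object: list with `spots`, `tracks` (all tracks),
#'   `kept` (filtered + classified tracks) and `summary`.
#' @export
track_comets <- function(frames, params = tracking_params(), pixel_size_um = 0.11,
                         centrosome_xy_um = NULL) {
  spots <- detect_spots_stack(frames, params, pixel_size_um)
  linked <- link_tracks(spots, params)
  tracks <- track_metrics(linked, params)
  kept <- filter_tracks(tracks, params)
  if (!is.null(centrosome_xy_um)) {
    kept <- classify_direction(kept, centrosome_xy_um)
    summ <- summarize_cell(kept, centrosome_xy_um, params)
  } else {
    summ <- summarize_cell(dplyr::mutate(kept, direction = NA_character_))
  }
  structure(list(spots = linked, tracks = tracks, kept = kept, summary = summ,
                 centrosome_xy_um = centrosome_xy_um, params = params),
            class = "comet_tracks")
}

#' Estimate the centrosome as the densest origin of tracks
#'
#' Convenience extension (the reference procedure locates the centrosome
#' manually): picks the maximum of an intensity-weighted 2D histogram of
#' track origin positions, bin width 1 um.
#'
#' @param spots Linked spots tibble.
#' @return `c(x, y)` in micrometers.
#' @export
estimate_centrosome <- function(spots) {
  origins <- spots |>
    dplyr::group_by(.data$track) |>
    dplyr::slice_min(.data$frame, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(origins) == 0) abort("no tracks to estimate a centrosome from")
  bx <- floor(origins$x_um); by <- floor(origins$y_um)
  key <- paste(bx, by)
  w <- tapply(origins$intensity, key, sum)
  top <- names(w)[which.max(w)]
  sel <- key == top
  c(x = mean(origins$x_um[sel]), y = mean(origins$y_um[sel]))
}

#' @export
print.comet_tracks <- function(x, ...) {
  cat(sprintf("<comet_tracks> %d spots, %d tracks (%d kept)\n",
              nrow(x$spots), nrow(x$tracks), nrow(x$kept)))
  if (!is.null(x$centrosome_xy_um))
    cat(sprintf("  fraction outward: %.3f\n", x$summary$fraction_outward))
  invisible(x)
}

#' @export
tidy.comet_tracks <- function(x, ...) x$kept

#' @export
glance.comet_tracks <- function(x, ...) x$summary
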