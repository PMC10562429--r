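# Ground-truthed phantom images and movies. These stand in for microscopy
# data in every test: DAB-like dark branched cells on a light background,
# CellMask-like bright cells, plus-tip comet movies with radial motion at
# known speed, and radially distributed intensity fields.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Parameters for the microglia phantom generator
#'
#' Defaults emulate Iba1/DAB-stained cortical microglia imaged at roughly
#' 0.46 um/px: dark somata of ~11 px radius carrying 4-6 thin branched
#' processes on a light background, with additive Gaussian noise at 5% of the
#' soma contrast. `morphology_class = "ameboid"` swaps the ramified layout for
#' enlarged, nearly branchless cells, mimicking reactive de-ramification.
#'
#' @param n_cells Number of cells to place.
#' @param image_shape Image height and width in pixels.
#' @param soma_radius_px Soma radius mean and sd, pixels.
#' @param n_branches Inclusive range of branch counts per cell.
#' @param branch_length_px Inclusive range of branch lengths, pixels.
#' @param branch_width_px Branch thickness, pixels.
#' @param soma_intensity,branch_intensity,background_intensity Absolute gray
#'   values (8-bit scale) of soma, branch and background pixels.
#' @param noise_sd Additive Gaussian noise sd, gray units.
#' @param morphology_class `"ramified"` or `"ameboid"`.
#' @param polarity `"dark_on_light"` (DAB) or `"bright_on_dark"` (fluorescence).
#' @param pixel_size_um Pixel calibration, micrometers per pixel.
#' @param rng_seed Integer seed; identical seeds give bit-identical phantoms.
#' @return A `phantom_params` list, validated.
#' @export
phantom_params <- function(n_cells = 12,
                           image_shape = c(512, 512),
                           soma_radius_px = c(mean = 13, sd = 0.8),
                           n_branches = c(5, 7),
                           branch_length_px = c(40, 70),
                           branch_width_px = 4,
                           soma_intensity = 100,
                           branch_intensity = 150,
                           background_intensity = 220,
                           noise_sd = 6,
                           morphology_class = c("ramified", "ameboid"),
                           polarity = c("dark_on_light", "bright_on_dark"),
                           pixel_size_um = 0.46,
                           rng_seed = NULL) {
  morphology_class <- match.arg(morphology_class)
  polarity <- match.arg(polarity)
  if (morphology_class == "ameboid") {
    # reactive morphology: larger rounded soma, hardly any processes
    if (missing(soma_radius_px)) soma_radius_px <- c(mean = 18, sd = 2)
    if (missing(n_branches)) n_branches <- c(0, 2)
    if (missing(branch_length_px)) branch_length_px <- c(8, 15)
  }
  if (polarity == "bright_on_dark" && missing(background_intensity) &&
      missing(soma_intensity) && missing(branch_intensity)) {
    background_intensity <- 20; soma_intensity <- 200; branch_intensity <- 140
  }
  p <- list(n_cells = as.integer(n_cells), image_shape = as.integer(image_shape),
            soma_radius_px = soma_radius_px, n_branches = as.integer(n_branches),
            branch_length_px = branch_length_px, branch_width_px = branch_width_px,
            soma_intensity = soma_intensity, branch_intensity = branch_intensity,
            background_intensity = background_intensity, noise_sd = noise_sd,
            morphology_class = morphology_class, polarity = polarity,
            pixel_size_um = pixel_size_um, rng_seed = rng_seed)
  if (p$n_cells < 0) abort("`n_cells` must be non-negative")
  if (length(p$image_shape) != 2 || any(p$image_shape < 32))
    abort("`image_shape` must be two dimensions of at least 32 px")
  if (abs(soma_intensity - background_intensity) <= 3 * noise_sd)
    abort("soma and background intensity must differ by more than 3 * noise_sd")
  if (p$soma_radius_px[[1]] <= 1) abort("soma radius must exceed 1 px")
  structure(p, class = "phantom_params")
}

# Stamp a filled disc into integer matrix `m` (returns modified matrix).
stamp_disc <- function(m, cy, cx, r, value) {
  nr <- nrow(m); nc <- ncol(m)
  r0 <- max(1L, floor(cy - r)); r1 <- min(nr, ceiling(cy + r))
  c0 <- max(1L, floor(cx - r)); c1 <- min(nc, ceiling(cx + r))
  if (r0 > r1 || c0 > c1) return(m)
  ys <- r0:r1; xs <- c0:c1
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  hit <- outer(dy2, dx2, "+") <= r^2
  sub <- m[ys, xs, drop = FALSE]
  sub[hit] <- value
  m[ys, xs] <- sub
  m
}

# TRUE if stamping a disc of radius r at (cy, cx) would come within 1 px of a
# label other than `self` (used to truncate branches before they fuse cells).
disc_conflicts <- function(lab, cy, cx, r, self) {
  nr <- nrow(lab); nc <- ncol(lab)
  rr <- r + 1
  r0 <- max(1L, floor(cy - rr)); r1 <- min(nr, ceiling(cy + rr))
  c0 <- max(1L, floor(cx - rr)); c1 <- min(nc, ceiling(cx + rr))
  ys <- r0:r1; xs <- c0:c1
  hit <- outer((ys - cy)^2, (xs - cx)^2, "+") <= rr^2
  vals <- lab[ys, xs, drop = FALSE][hit]
  any(vals != 0L & vals != self)
}

#' Generate a ground-truthed microglia phantom
#'
#' Places `n_cells` non-overlapping somata on a jittered grid and grows each
#' branch as a bounded-turning random walk from the soma rim. Branches are
#' truncated rather than allowed to touch a neighboring cell, so every label
#' remains one 8-connected component. True per-cell descriptors are measured
#' directly on the returned ground-truth label map.
#'
#' @param params A [phantom_params()] object.
#' @return List with `image` (a [gray_image()]), `labels` (ground-truth
#'   [label_map()]), `type` (integer matrix: 1 soma, 2 branch) and `cells`
#'   (tibble of true per-cell descriptors from [measure_cells()]).
#' @export
generate_microglia_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  with_seed_(params$rng_seed, {
    nr <- params$image_shape[1]; nc <- params$image_shape[2]
    lab <- matrix(0L, nr, nc)
    type <- matrix(0L, nr, nc)
    n <- params$n_cells
    soma_mu <- params$soma_radius_px[[1]]; soma_sd <- params$soma_radius_px[[2]]
    margin <- ceiling(soma_mu + 3 * soma_sd + 3)
    if (n > 0) {
      # jittered-grid placement keeps somata apart at densities where plain
      # rejection sampling jams
      grid_r <- max(1L, round(sqrt(n * nr / nc)))
      grid_c <- ceiling(n / grid_r)
      while (grid_r * grid_c < n) grid_c <- grid_c + 1L
      cell_h <- (nr - 2 * margin) / grid_r
      cell_w <- (nc - 2 * margin) / grid_c
      if (min(cell_h, cell_w) < 2.2 * (soma_mu + 3 * soma_sd))
        abort("`n_cells` too dense for `image_shape`: somata cannot be placed without overlap")
      slots <- expand.grid(gr = seq_len(grid_r), gc = seq_len(grid_c))
      slots <- slots[sample.int(nrow(slots), n), , drop = FALSE]
      jit_h <- 0.3 * cell_h; jit_w <- 0.3 * cell_w
      centers <- cbind(
        y = margin + (slots$gr - 0.5) * cell_h + runif(n, -jit_h, jit_h),
        x = margin + (slots$gc - 0.5) * cell_w + runif(n, -jit_w, jit_w))
      # truncated normal: keeps every soma within the size regime the seed
      # detection is parameterized for
      radii <- pmin(pmax(rnorm(n, soma_mu, soma_sd),
                         pmax(2, soma_mu - 2.5 * soma_sd)),
                    soma_mu + 2.5 * soma_sd)
      # verify the invariant explicitly
      if (n > 1) {
        d <- as.matrix(stats::dist(centers))
        diag(d) <- Inf
        if (any(d < outer(radii, radii, "+") + 2))
          abort("soma placement failed: overlapping somata") # nocov
      }
      for (i in seq_len(n)) {
        lab <- stamp_disc(lab, centers[i, 1], centers[i, 2], radii[i], i)
        type <- stamp_disc(type, centers[i, 1], centers[i, 2], radii[i], 1L)
      }
      half_w <- params$branch_width_px / 2
      for (i in seq_len(n)) {
        nb <- if (params$n_branches[2] >= params$n_branches[1])
          sample(seq(params$n_branches[1], params$n_branches[2]), 1) else params$n_branches[1]
        if (nb == 0) next
        base_angles <- runif(1, 0, 2 * pi) + seq(0, 2 * pi, length.out = nb + 1)[-(nb + 1)]
        for (theta0 in base_angles) {
          len <- runif(1, params$branch_length_px[1], params$branch_length_px[2])
          theta <- theta0 + runif(1, -0.3, 0.3)
          py <- centers[i, 1] + (radii[i] - 0.5) * sin(theta)
          px <- centers[i, 2] + (radii[i] - 0.5) * cos(theta)
          travelled <- 0
          while (travelled < len) {
            if (py < 2 + half_w || py > nr - 1 - half_w ||
                px < 2 + half_w || px > nc - 1 - half_w) break
            if (disc_conflicts(lab, py, px, half_w, i)) break
            lab <- stamp_disc(lab, py, px, half_w, i)
            type <- stamp_disc(type, py, px, half_w, 2L)
            theta <- theta + runif(1, -0.25, 0.25)
            py <- py + sin(theta); px <- px + cos(theta)
            travelled <- travelled + 1
          }
        }
      }
      # soma pixels dominate over branch stamps that crossed them
      for (i in seq_len(n)) {
        type <- stamp_disc(type, centers[i, 1], centers[i, 2], radii[i], 1L)
      }
    }
    img <- matrix(params$background_intensity, nr, nc)
    img[type == 1L] <- params$soma_intensity
    img[type == 2L] <- params$branch_intensity
    if (params$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    img <- pmin(pmax(img, 0), 255)
    gi <- gray_image(img, params$pixel_size_um,
                     if (params$polarity == "dark_on_light") "signal_dark" else "signal_bright")
    lm <- label_map(lab, params$pixel_size_um)
    cells <- measure_cells(lm)
    cells$morphology_class <- params$morphology_class
    list(image = gi, labels = lm, type = type, cells = cells)
  })
}

#' Parameters for synthetic plus-tip comet movies
#'
#' Defaults emulate EB-comet movies acquired at 1 frame per second for 300
#' frames on a 100x confocal (0.11 um/px): Gaussian comets of known speed
#' moving radially outward from (or inward toward) a fixed centrosome.
#'
#' @param n_tracks Number of comet tracks.
#' @param image_shape Frame height and width, pixels.
#' @param centrosome_xy Centrosome position `c(x, y)` in pixels; defaults to
#'   the image center. Must lie inside the image.
#' @param fraction_outward Proportion of tracks growing away from the
#'   centrosome, in \[0, 1\].
#' @param speed_um_s Comet speed mean and sd, micrometers per second.
#' @param frame_interval_s Time between frames, seconds.
#' @param n_frames Number of frames (>= 2).
#' @param psf_sigma_px Gaussian spot sigma, pixels.
#' @param spot_intensity Peak spot amplitude, gray units.
#' @param background_intensity Constant background, gray units.
#' @param noise_sd Additive Gaussian noise sd, gray units.
#' @param pixel_size_um Calibration, micrometers per pixel.
#' @param track_lifetime_frames Inclusive range of track lifetimes, frames.
#' @param angular_jitter_sd Per-step jitter of the motion angle, radians.
#' @param rng_seed Integer seed.
#' @return A `comet_movie_params` list, validated.
#' @export
comet_movie_params <- function(n_tracks = 20,
                               image_shape = c(256, 256),
                               centrosome_xy = NULL,
                               fraction_outward = 1,
                               speed_um_s = c(mean = 0.1, sd = 0.02),
                               frame_interval_s = 1,
                               n_frames = 300,
                               psf_sigma_px = 2.6,
                               spot_intensity = 100,
                               background_intensity = 10,
                               noise_sd = 20,
                               pixel_size_um = 0.11,
                               track_lifetime_frames = c(20, 50),
                               angular_jitter_sd = 0.05,
                               rng_seed = NULL) {
  if (is.null(centrosome_xy)) centrosome_xy <- c(image_shape[2] / 2, image_shape[1] / 2)
  p <- list(n_tracks = as.integer(n_tracks), image_shape = as.integer(image_shape),
            centrosome_xy = centrosome_xy, fraction_outward = fraction_outward,
            speed_um_s = speed_um_s, frame_interval_s = frame_interval_s,
            n_frames = as.integer(n_frames), psf_sigma_px = psf_sigma_px,
            spot_intensity = spot_intensity, background_intensity = background_intensity,
            noise_sd = noise_sd, pixel_size_um = pixel_size_um,
            track_lifetime_frames = as.integer(track_lifetime_frames),
            angular_jitter_sd = angular_jitter_sd, rng_seed = rng_seed)
  if (p$n_frames < 2) abort("`n_frames` must be at least 2")
  if (p$fraction_outward < 0 || p$fraction_outward > 1)
    abort("`fraction_outward` must lie in [0, 1]")
  if (p$speed_um_s[[1]] <= 0) abort("mean speed must be positive")
  if (p$centrosome_xy[1] < 1 || p$centrosome_xy[1] > p$image_shape[2] ||
      p$centrosome_xy[2] < 1 || p$centrosome_xy[2] > p$image_shape[1])
    abort("`centrosome_xy` must lie inside the image")
  if (p$track_lifetime_frames[2] > p$n_frames)
    p$track_lifetime_frames[2] <- p$n_frames
  if (p$track_lifetime_frames[1] > p$track_lifetime_frames[2])
    p$track_lifetime_frames[1] <- p$track_lifetime_frames[2]
  structure(p, class = "comet_movie_params")
}

#' Generate a synthetic plus-tip comet movie with ground truth
#'
#' Each comet travels radially at a per-track speed drawn from the configured
#' distribution, with small angular jitter; outward comets start near the
#' centrosome, inward comets start at larger radius, so distance to the
#' centrosome changes monotonically along every track.
#'
#' @param params A [comet_movie_params()] object.
#' @return List with `frames` (list of matrices), `spots` (tibble of true
#'   per-frame positions: `track`, `frame`, `x_px`, `y_px`, `x_um`, `y_um`)
#'   and `tracks` (tibble: `track`, `direction`, `speed_um_s`, `start_frame`,
#'   `n_spots`, `d0_um`, `dn_um`).
#' @export
generate_comet_movie <- function(params = comet_movie_params()) {
  stopifnot(inherits(params, "comet_movie_params"))
  with_seed_(params$rng_seed, {
    nr <- params$image_shape[1]; nc <- params$image_shape[2]
    cx <- params$centrosome_xy[1]; cy <- params$centrosome_xy[2]
    n <- params$n_tracks
    n_out <- round(params$fraction_outward * n)
    dirs <- sample(c(rep("outward", n_out), rep("inward", n - n_out)))
    step_px <- params$speed_um_s[[1]] * params$frame_interval_s / params$pixel_size_um
    max_life <- params$track_lifetime_frames[2]
    max_travel <- max_life * (params$speed_um_s[[1]] + 3 * max(params$speed_um_s[[2]], 0)) *
      params$frame_interval_s / params$pixel_size_um
    r_edge <- min(cx - 1, nc - cx, cy - 1, nr - cy) - 3 * params$psf_sigma_px
    spots <- vector("list", n)
    trk <- vector("list", n)
    for (i in seq_len(n)) {
      life <- if (params$track_lifetime_frames[1] < params$track_lifetime_frames[2])
        sample(seq(params$track_lifetime_frames[1], params$track_lifetime_frames[2]), 1)
      else params$track_lifetime_frames[1]
      life <- min(life, params$n_frames)
      start <- if (params$n_frames - life >= 1) sample.int(params$n_frames - life + 1, 1) else 1L
      speed <- max(0.05 * params$speed_um_s[[1]],
                   rnorm(1, params$speed_um_s[[1]], max(params$speed_um_s[[2]], 0)))
      sp_px <- speed * params$frame_interval_s / params$pixel_size_um
      phi <- runif(1, 0, 2 * pi)
      travel <- life * sp_px
      if (dirs[i] == "outward") {
        r0 <- runif(1, 4, max(10, min(0.4 * r_edge, r_edge - travel - 5)))
      } else {
        r0 <- runif(1, min(0.9 * r_edge, travel + 10), 0.95 * r_edge)
      }
      x <- cx + r0 * cos(phi); y <- cy + r0 * sin(phi)
      xs <- numeric(life); ys <- numeric(life)
      # comets travel along a straight microtubule: the heading is fixed at
      # nucleation (radial, plus a small constant tilt), with per-step jitter
      base <- if (dirs[i] == "outward") phi else phi + pi
      base <- base + rnorm(1, 0, params$angular_jitter_sd)
      for (t in seq_len(life)) {
        xs[t] <- x; ys[t] <- y
        ang <- base + rnorm(1, 0, params$angular_jitter_sd)
        x <- x + sp_px * cos(ang); y <- y + sp_px * sin(ang)
      }
      frames_i <- seq(start, start + life - 1)
      spots[[i]] <- tibble(track = i, frame = frames_i, x_px = xs, y_px = ys)
      d0 <- sqrt((xs[1] - cx)^2 + (ys[1] - cy)^2) * params$pixel_size_um
      dn <- sqrt((xs[life] - cx)^2 + (ys[life] - cy)^2) * params$pixel_size_um
      trk[[i]] <- tibble(track = i, direction = dirs[i], speed_um_s = speed,
                         start_frame = start, n_spots = life, d0_um = d0, dn_um = dn)
    }
    spots <- dplyr::bind_rows(spots)
    spots$x_um <- (spots$x_px - 1) * params$pixel_size_um
    spots$y_um <- (spots$y_px - 1) * params$pixel_size_um
    tracks <- dplyr::bind_rows(trk)
    frames <- render_comet_frames(spots, params)
    list(frames = frames, spots = spots, tracks = tracks, params = params)
  })
}

render_comet_frames <- function(spots, params) {
  nr <- params$image_shape[1]; nc <- params$image_shape[2]
  sig <- params$psf_sigma_px
  ext <- ceiling(4 * sig)
  lapply(seq_len(params$n_frames), function(t) {
    f <- matrix(params$background_intensity, nr, nc)
    st <- spots[spots$frame == t, , drop = FALSE]
    for (k in seq_len(nrow(st))) {
      x0 <- st$x_px[k]; y0 <- st$y_px[k]
      r0 <- max(1L, floor(y0 - ext)); r1 <- min(nr, ceiling(y0 + ext))
      c0 <- max(1L, floor(x0 - ext)); c1 <- min(nc, ceiling(x0 + ext))
      if (r0 > r1 || c0 > c1) next
      ys <- r0:r1; xs <- c0:c1
      g <- params$spot_intensity *
        exp(-outer((ys - y0)^2, (xs - x0)^2, "+") / (2 * sig^2))
      f[ys, xs] <- f[ys, xs] + g
    }
    if (params$noise_sd > 0)
      f <- f + matrix(rnorm(nr * nc, 0, params$noise_sd), nr, nc)
    pmax(f, 0)
  })
}

#' Generate a radially distributed intensity field
#'
#' Isotropic Gaussian intensity centered at `center`, used as a test input for
#' radial-profile statistics (the 80%-cumulative-density radius).
#'
#' @param center `c(x, y)` center in pixels; must lie inside the image.
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @param shape Image height and width in pixels.
#' @param amplitude Peak amplitude above background, gray units.
#' @param background Constant background, gray units.
#' @param noise_sd Additive Gaussian noise sd, gray units.
#' @param pixel_size_um Calibration, micrometers per pixel.
#' @param seed Integer seed for the noise.
#' @return A [gray_image()].
#' @export
generate_radial_intensity_image <- function(center, sigma_px, shape = c(256, 256),
                                            amplitude = 100, background = 0,
                                            noise_sd = 0, pixel_size_um = 1,
                                            seed = NULL) {
  if (sigma_px <= 0) abort("`sigma_px` must be positive")
  if (center[1] < 1 || center[1] > shape[2] || center[2] < 1 || center[2] > shape[1])
    abort("`center` must lie inside the image")
  with_seed_(seed, {
    ys <- seq_len(shape[1]); xs <- seq_len(shape[2])
    d2 <- outer((ys - center[2])^2, (xs - center[1])^2, "+")
    img <- background + amplitude * exp(-d2 / (2 * sigma_px^2))
    if (noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, noise_sd), shape[1], shape[2])
    gray_image(img, pixel_size_um, "signal_bright")
  })
}
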