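test_that("LoG detection finds synthetic spots to sub-pixel accuracy", {
  frame <- matrix(5, 64, 64)
  ys <- seq_len(64)
  for (pos in list(c(20.3, 31.7), c(45.2, 12.4))) {
    frame <- frame + 100 * exp(-outer((ys - pos[2])^2, (ys - pos[1])^2, "+") / (2 * 2.57^2))
  }
  sp <- detect_spots(frame, tracking_params(detection_threshold = 30), 0.11)
  expect_equal(nrow(sp), 2)
  sp <- sp[order(sp$x_px), ]
  expect_lt(sqrt((sp$x_px[1] - 20.3)^2 + (sp$y_px[1] - 31.7)^2), 0.25)
  expect_lt(sqrt((sp$x_px[2] - 45.2)^2 + (sp$y_px[2] - 12.4)^2), 0.25)
  # blank frame yields nothing
  expect_equal(nrow(detect_spots(matrix(5, 64, 64),
                                 tracking_params(detection_threshold = 5), 0.11)), 0)
  # two spots 6 px apart resolve as two detections
  frame2 <- matrix(0, 64, 64)
  for (x0 in c(30, 36))
    frame2 <- frame2 + 100 * exp(-outer((ys - 32)^2, (ys - x0)^2, "+") / (2 * 2.57^2))
  expect_equal(nrow(detect_spots(frame2, tracking_params(detection_threshold = 30), 0.11)), 2)
  expect_error(detect_spots(frame, tracking_params(log_radius_um = 0.4), pixel_size_um = 0.5),
               "below 1 px")
})

drift_spots <- function(step_um, n, start = c(1, 1)) {
  tibble::tibble(frame = seq_len(n),
                 x_px = NA_real_, y_px = NA_real_,
                 x_um = start[1] + step_um * (seq_len(n) - 1), y_um = start[2],
                 intensity = 1, quality = 10)
}

test_that("linking respects the 1.5 um limit and bridges small gaps", {
  tp <- tracking_params()
  # 1.0 um/frame drift stays one track
  linked <- link_tracks(drift_spots(1.0, 8), tp)
  expect_equal(dplyr::n_distinct(linked$track), 1)
  # 2.0 um jumps exceed the limit: every spot its own track
  linked2 <- link_tracks(drift_spots(2.0, 5), tp)
  expect_equal(dplyr::n_distinct(linked2$track), 5)
  # a 3-frame interruption re-appearing 0.4 um away is bridged
  sp <- drift_spots(0.1, 10)
  sp <- sp[sp$frame %in% c(1:4, 8:10), ]
  linked3 <- link_tracks(sp, tp)
  expect_equal(dplyr::n_distinct(linked3$track), 1)
  # but not when the gap distance exceeds 0.5 um
  sp2 <- sp
  sp2$x_um[sp2$frame >= 8] <- sp2$x_um[sp2$frame >= 8] + 1.0
  linked4 <- link_tracks(sp2, tp)
  expect_equal(dplyr::n_distinct(linked4$track), 2)
})

test_that("frame-pair assignment equals exhaustive minimal matching", {
  set.seed(77)
  for (rep in 1:40) {
    n1 <- sample(0:6, 1); n2 <- sample(0:6, 1)
    a <- cbind(runif(n1, 0, 8), runif(n1, 0, 8))
    b <- cbind(runif(n2, 0, 8), runif(n2, 0, 8))
    got <- gliascope:::match_frame_pair(a, b, max_dist = 2.5)
    if (n1 == 0) { expect_length(got, 0); next }
    want <- oracle_matching(a, b, max_dist = 2.5)
    expect_equal(matching_cost(got, a, b), matching_cost(want, a, b),
                 tolerance = 1e-9)
  }
})

test_that("track filtering drops short and non-linear tracks", {
  tp <- tracking_params()
  straight <- track_metrics(link_tracks(drift_spots(0.5, 10), tp), tp)
  expect_equal(straight$confinement_ratio, 1)
  expect_equal(nrow(filter_tracks(straight, tp)), 1)
  short <- track_metrics(link_tracks(drift_spots(0.5, 3), tp), tp)
  expect_equal(nrow(filter_tracks(short, tp)), 0)       # 3 spots < 4
  # out-and-back: net displacement ~ 0
  sp <- drift_spots(0.5, 9)
  sp$x_um <- 1 + 0.5 * c(0:4, 3:0)
  back <- track_metrics(link_tracks(sp, tp), tp)
  expect_lt(back$confinement_ratio, 0.2)
  expect_equal(nrow(filter_tracks(back, tp)), 0)
})

test_that("direction is outward only when the track ends strictly farther", {
  tr <- tibble::tibble(track = 1:3,
                       x0_um = c(2, 5, 4), y0_um = 0,
                       xn_um = c(5, 2, 4), yn_um = 0)
  out <- classify_direction(tr, centrosome_xy = c(0, 0))
  expect_equal(out$direction, c("outward", "inward", "inward"))  # tie is inward
  expect_equal(out$d0_um, c(2, 5, 4))
  expect_equal(out$dn_um, c(5, 2, 4))
  expect_error(classify_direction(tr), "centrosome")
})

test_that("mirroring a movie through the centrosome swaps outward and inward", {
  mv <- generate_comet_movie(comet_movie_params(fraction_outward = 0.7, n_frames = 50,
                                                rng_seed = 8))
  cx <- mv$params$centrosome_xy[1] * 0.11; cy <- mv$params$centrosome_xy[2] * 0.11
  tm <- tibble::tibble(track = mv$tracks$track,
                       x0_um = NA, y0_um = NA, xn_um = NA, yn_um = NA)
  for (i in seq_len(nrow(tm))) {
    sp <- mv$spots[mv$spots$track == i, ]
    tm$x0_um[i] <- sp$x_um[1]; tm$y0_um[i] <- sp$y_um[1]
    tm$xn_um[i] <- sp$x_um[nrow(sp)]; tm$yn_um[i] <- sp$y_um[nrow(sp)]
  }
  ctr <- c((mv$params$centrosome_xy[1] - 1) * 0.11, (mv$params$centrosome_xy[2] - 1) * 0.11)
  fwd <- classify_direction(tm, ctr)
  mirrored <- dplyr::mutate(tm,
                            x0_um = 2 * ctr[1] - x0_um, xn_um = 2 * ctr[1] - xn_um,
                            y0_um = 2 * ctr[2] - y0_um, yn_um = 2 * ctr[2] - yn_um)
  bwd <- classify_direction(mirrored, ctr)
  expect_identical(fwd$direction, bwd$direction)  # point reflection keeps distances
  expect_equal(fwd$d0_um, bwd$d0_um)
  # reflection about the centrosome with sign flip of radial motion:
  # exchanging first and last spots must swap every direction
  swapped <- classify_direction(
    dplyr::mutate(tm, tmp = x0_um, x0_um = xn_um, xn_um = tmp,
                  tmp2 = y0_um, y0_um = yn_um, yn_um = tmp2), ctr)
  expect_true(all(swapped$direction != fwd$direction |
                    abs(fwd$d0_um - fwd$dn_um) < 1e-12))
})

test_that("spot insertion order does not change linked results", {
  mv <- generate_comet_movie(comet_movie_params(n_tracks = 6, n_frames = 30,
                                                rng_seed = 12))
  tp <- tracking_params(detection_threshold = 40)
  sp <- detect_spots_stack(mv$frames, tp, 0.11)
  set.seed(1)
  shuffled <- sp[sample.int(nrow(sp)), ]
  a <- track_metrics(link_tracks(sp, tp), tp)
  b <- track_metrics(link_tracks(shuffled, tp), tp)
  key <- function(d) d[order(d$first_frame, d$x0_um, d$y0_um),
                       c("n_spots", "path_length_um", "net_displacement_um")]
  expect_equal(key(a), key(b), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a synthetic outward movie is summarized faithfully", {
  mv <- generate_comet_movie(comet_movie_params(fraction_outward = 1, n_frames = 60,
                                                track_lifetime_frames = c(20, 50),
                                                rng_seed = 3))
  tp <- tracking_params(detection_threshold = 40)
  centro <- (mv$params$centrosome_xy - 1) * mv$params$pixel_size_um
  tk <- track_comets(mv$frames, tp, pixel_size_um = 0.11, centrosome_xy_um = centro)
  expect_equal(tk$summary$fraction_outward, 1)
  expect_lt(abs(tk$summary$mean_speed_um_s / mean(mv$tracks$speed_um_s) - 1), 0.1)
  expect_lt(abs(tk$summary$n_tracks - 20) / 20, 0.25)
  expect_s3_class(tidy(tk), "tbl_df")
  expect_equal(glance(tk)$n_tracks, nrow(tk$kept))
  # empty movie
  empty <- track_comets(replicate(5, matrix(0, 32, 32), simplify = FALSE),
                        tracking_params(detection_threshold = 5), 0.11,
                        centrosome_xy_um = c(1, 1))
  expect_equal(empty$summary$n_tracks, 0)
})
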