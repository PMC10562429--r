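disc_mask <- function(r, pad = 11) {
  n <- 2 * r + 2 * pad + 1
  ctr <- r + pad + 1
  s <- seq_len(n)
  outer((s - ctr)^2, (s - ctr)^2, "+") <= r^2
}

test_that("a rasterized disc is round: high circularity, low ramification", {
  mask <- disc_mask(50)
  rec <- measure_cells(matrix(as.integer(mask), nrow(mask)))
  expect_equal(rec$area_px, sum(mask))
  expect_lt(abs(rec$area_px / (pi * 50^2) - 1), 0.02)
  expect_gte(rec$circularity, 0.95)
  expect_lte(rec$ramification_index, 0.05)
  expect_equal(rec$inscribed_radius_px, 50, tolerance = 0.03)
  expect_equal(rec$feret_diameter_px, 101, tolerance = 0.02)
})

test_that("a thin line is maximally ramified with geodesic diameter its length", {
  mask <- matrix(FALSE, 21, 120)
  mask[11, 11:110] <- TRUE
  rec <- measure_cells(matrix(as.integer(mask), nrow(mask)))
  expect_gte(rec$ramification_index, 0.9)
  expect_equal(rec$geodesic_diameter_px, 99, tolerance = 2 / 99)
  expect_equal(rec$feret_diameter_px, sqrt(100^2 + 1), tolerance = 0.02)
})

test_that("Feret diameter of a filled rectangle is its corner diagonal", {
  mask <- matrix(FALSE, 40, 40)
  mask[11:20, 11:30] <- TRUE
  rec <- measure_cells(matrix(as.integer(mask), nrow(mask)))
  expect_equal(rec$feret_diameter_px, sqrt(10^2 + 20^2), tolerance = 1 / 22.4)
})

test_that("units scale with the pixel calibration", {
  mask <- disc_mask(20)
  rec <- measure_cells(label_map(matrix(as.integer(mask), nrow(mask)),
                                 pixel_size_um = 0.46))
  expect_equal(rec$area_um2, rec$area_px * 0.46^2)
  expect_equal(rec$feret_diameter_um, rec$feret_diameter_px * 0.46)
  expect_equal(rec$geodesic_diameter_um, rec$geodesic_diameter_px * 0.46)
})

test_that("geodesic diameter follows the pixel-graph metric", {
  line <- matrix(FALSE, 5, 60)
  line[3, 6:55] <- TRUE                                  # 50 px straight line
  expect_equal(geodesic_diameter(line), 49)
  l_shape <- matrix(FALSE, 50, 50)
  l_shape[10:39, 10] <- TRUE                             # 30 px arm
  l_shape[39, 10:49] <- TRUE                             # 40 px arm
  expect_equal(geodesic_diameter(l_shape), oracle_geodesic_diameter(l_shape),
               tolerance = 1e-9)
  expect_error(geodesic_diameter(matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2) &
                                   diag(2) < 0), "empty")
  disc2 <- matrix(FALSE, 9, 9); disc2[5, 5] <- TRUE; disc2[1, 1] <- TRUE
  expect_error(geodesic_diameter(disc2), "connected")
})

test_that("geodesic diameter matches the all-pairs oracle on random masks", {
  set.seed(33)
  for (rep in 1:12) {
    mask <- random_connected_mask(sample(10:22, 1), sample(10:22, 1))
    expect_equal(geodesic_diameter(mask), oracle_geodesic_diameter(mask),
                 tolerance = 2 / max(1, oracle_geodesic_diameter(mask)))
  }
  # and on a filled disc, where the chamfer metric exceeds the Euclidean 2r
  disc <- disc_mask(20)
  expect_equal(geodesic_diameter(disc), oracle_geodesic_diameter(disc),
               tolerance = 1e-9)
})

test_that("upscaling a mask doubles size measures and preserves circularity", {
  # circularity under doubled resolution: compare the same continuous shape
  # rasterized at 1x and 2x (blocky pixel replication adds staircase boundary
  # that any intercept-based perimeter estimator counts)
  a0 <- measure_cells(matrix(as.integer(disc_mask(25)), 2 * 25 + 23))
  b0 <- measure_cells(matrix(as.integer(disc_mask(50)), 2 * 50 + 23))
  expect_equal(b0$circularity / a0$circularity, 1, tolerance = 0.03)
  # length measures on a ramified phantom cell
  ph <- generate_microglia_phantom(phantom_params(n_cells = 1, image_shape = c(256, 256),
                                                  rng_seed = 14))
  mask <- ph$labels$labels == 1
  big <- mask[rep(seq_len(nrow(mask)), each = 2), rep(seq_len(ncol(mask)), each = 2)]
  a <- measure_cells(matrix(as.integer(mask), nrow(mask)))
  b <- measure_cells(matrix(as.integer(big), nrow(big)))
  expect_equal(b$feret_diameter_px / a$feret_diameter_px, 2, tolerance = 0.05)
  expect_equal(b$geodesic_diameter_px / a$geodesic_diameter_px, 2, tolerance = 0.05)
  expect_equal(b$inscribed_radius_px / a$inscribed_radius_px, 2, tolerance = 0.05)
})

test_that("descriptor invariants hold on phantom cells", {
  ph <- generate_microglia_phantom(phantom_params(n_cells = 8, rng_seed = 19))
  cells <- ph$cells
  expect_true(all(cells$circularity > 0 & cells$circularity <= 1))
  expect_true(all(cells$ramification_index >= 0 & cells$ramification_index < 1))
  expect_true(all(cells$inscribed_radius_px <= cells$feret_diameter_px / 2 + 1))
  expect_true(all(cells$geodesic_diameter_px >= cells$feret_diameter_px - 2))
  expect_error(measure_cell(ph$labels, 99), "not present")
})

test_that("cell density is count per area and invariant to relabeling", {
  m <- matrix(0L, 50, 50)
  m[2:11, 2:11] <- 5L; m[20:29, 20:29] <- 9L; m[40:49, 40:49] <- 2L
  expect_equal(cell_density(label_map(m), 0.01), 300)
  expect_equal(cell_density(label_map(gliascope:::relabel_contiguous(m)), 0.01), 300)
  expect_equal(cell_density(label_map(matrix(0L, 5, 5)), 0.5), 0)
  expect_error(cell_density(label_map(m), 0), "positive")
})

test_that("per-animal aggregation is the mean of section means", {
  cells <- tibble::tibble(
    animal = c("m1", "m1", "m1", "m2"),
    section = c("s1", "s1", "s2", "s1"),
    ramification_index = c(0.7, 0.9, 0.9, 0.5))
  out <- aggregate_by_group(cells)
  # animal m1: section means are 0.8 and 0.9 -> 0.85, not the pooled 0.833
  expect_equal(out$ramification_index[out$animal == "m1"], 0.85)
  expect_equal(out$ramification_index[out$animal == "m2"], 0.5)
  expect_equal(out$n_sections, c(2, 1))
  expect_error(aggregate_by_group(dplyr::select(cells, -section)), "section")
})
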