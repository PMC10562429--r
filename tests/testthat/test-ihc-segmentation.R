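test_that("preprocessing flattens constant images and inverts dark stain", {
  sp <- segmentation_params()
  flat <- preprocess(matrix(120, 64, 64), sp, polarity = "signal_dark")
  expect_true(all(abs(flat$pixels) < 1e-6))
  # dark blob on light field becomes the brightest structure
  img <- matrix(200, 128, 128)
  img[60:70, 60:70] <- 50
  out <- preprocess(img, sp, polarity = "signal_dark")
  w <- which(out$pixels == max(out$pixels), arr.ind = TRUE)
  expect_true(all(w[, 1] %in% 58:72 & w[, 2] %in% 58:72))
  expect_identical(out$polarity, "signal_bright")
  expect_error(preprocess(matrix(NaN, 4, 4), sp), "NaN|empty")
})

test_that("gaussian smoothing is mass-preserving and symmetric", {
  # delta response through the same blur the pipeline applies
  img <- matrix(0, 65, 65)
  img[33, 33] <- 100
  out <- gliascope:::as_img_matrix(EBImage::gblur(img, 1))
  expect_equal(sum(out), 100, tolerance = 0.01)
  expect_equal(out[33 - 3, 33], out[33 + 3, 33], tolerance = 1e-8)
  expect_equal(out[33, 33 - 3], out[33 + 3, 33], tolerance = 1e-8)
})

test_that("seed and watershed thresholds follow their formulas", {
  img <- matrix(c(255, 175, 215, 215), 2, 2)  # max 255
  expect_equal(compute_seed_threshold(img, 2), 255 - 2 * sd(c(255, 175, 215, 215)))
  expect_equal(compute_seed_threshold(img, 0), 255)
  expect_equal(compute_watershed_threshold(img, 0), mean(img))
  expect_equal(compute_watershed_threshold(img, 0.5),
               mean(img) + 0.5 * sd(as.vector(img)))
  cst <- matrix(42, 8, 8)
  expect_equal(compute_seed_threshold(cst, 3), 42)     # sd = 0
  expect_equal(compute_watershed_threshold(cst, 3), 42)
})

test_that("soma detection applies the 300 px area floor to supra-Th1 components", {
  sp <- segmentation_params()
  img <- matrix(0, 100, 100)
  img[10:29, 10:29] <- 255                       # 400 px plateau
  seeds <- detect_somata(gray_image(img), sp, th1 = 200)
  expect_equal(n_labels(seeds), 1)
  img2 <- matrix(0, 100, 100)
  img2[10:19, 10:19] <- 255                      # 100 px: below the floor
  expect_equal(n_labels(detect_somata(gray_image(img2), sp, th1 = 200)), 0)
  # two plateaus >= 300 px separated by sub-threshold pixels give two seeds
  img3 <- matrix(0, 100, 100)
  img3[10:29, 10:29] <- 255
  img3[10:29, 40:59] <- 255
  img3[15, 30:39] <- 100                         # bridge below Th1
  seeds3 <- detect_somata(gray_image(img3), sp, th1 = 200)
  expect_equal(n_labels(seeds3), 2)
})

test_that("seeded watershed obeys seed connectivity and the Th2 floor", {
  # single uniform supra-th2 blob with an interior seed takes the whole blob
  img <- matrix(0, 40, 40)
  img[10:30, 10:30] <- 100
  seeds <- matrix(0L, 40, 40); seeds[20, 20] <- 1L
  out <- seeded_watershed(gray_image(img), label_map(seeds), th2 = 50)
  expect_true(all((out$labels == 1) == (img >= 50)))
  # a supra-th2 blob without a seed stays background
  img2 <- img
  img2[5:8, 35:38] <- 200
  out2 <- seeded_watershed(gray_image(img2), label_map(seeds), th2 = 50)
  expect_true(all(out2$labels[5:8, 35:38] == 0))
  # labeled pixels never fall below th2; every label contains its seed
  expect_true(all(img2[out2$labels > 0] >= 50))
  expect_equal(out2$labels[20, 20], 1L)
})

test_that("a dumbbell splits at its lowest-intensity neck, as the oracle says", {
  set.seed(21)
  img <- matrix(runif(30 * 50, 0, 10), 30, 50)
  ys <- 1:30; xs <- 1:50
  lobe1 <- outer((ys - 15)^2, (xs - 12)^2, "+") <= 81
  lobe2 <- outer((ys - 15)^2, (xs - 38)^2, "+") <= 81
  neck <- outer(abs(ys - 15), abs(xs - 25), function(a, b) a <= 2 & b <= 6)
  img[lobe1] <- img[lobe1] + 100
  img[lobe2] <- img[lobe2] + 100
  img[neck] <- 60 + runif(sum(neck))
  seeds <- matrix(0L, 30, 50)
  seeds[15, 12] <- 1L; seeds[15, 38] <- 2L
  out <- seeded_watershed(gray_image(img), label_map(seeds), th2 = 40)
  expect_identical(out$labels, oracle_watershed(img, seeds, 40))
  expect_equal(sort(unique(as.vector(out$labels))), c(0L, 1L, 2L))
  # each lobe belongs to its own seed
  expect_true(all(out$labels[lobe1] == 1L))
  expect_true(all(out$labels[lobe2] == 2L))
})

test_that("watershed equals the brute-force priority-flood oracle on random images", {
  set.seed(42)
  for (rep in 1:30) {
    nr <- sample(10:24, 1); nc <- sample(10:24, 1)
    img <- random_smooth_image(nr, nc, smooth_sigma = sample(c(0, 1), 1))
    ns <- sample(1:4, 1)
    seeds <- matrix(0L, nr, nc)
    seeds[sample(nr * nc, ns)] <- seq_len(ns)
    th2 <- quantile(img, runif(1, 0.2, 0.8))
    expect_identical(gliascope:::cpp_seeded_watershed(img, seeds, th2),
                     oracle_watershed(img, seeds, th2))
  }
})

test_that("every label contains exactly one seed and respects Th2", {
  set.seed(13)
  for (rep in 1:10) {
    img <- random_smooth_image(20, 20)
    seeds <- matrix(0L, 20, 20)
    ns <- sample(2:4, 1)
    seeds[sample(400, ns)] <- seq_len(ns)
    th2 <- quantile(img, 0.3)
    out <- gliascope:::cpp_seeded_watershed(img, seeds, th2)
    for (id in seq_len(ns)) {
      expect_equal(sum(seeds[out == id] == id), sum(seeds == id))
      expect_equal(sum(seeds == id & out != id), 0)
    }
    expect_true(all(img[out > 0 & seeds == 0] >= th2))
  }
})

test_that("raising Th2 never grows a cell; raising the area filter never adds cells", {
  set.seed(31)
  img <- random_smooth_image(40, 40)
  seeds <- matrix(0L, 40, 40)
  seeds[cbind(c(10, 30), c(10, 30))] <- 1:2
  th_lo <- quantile(img, 0.2); th_hi <- quantile(img, 0.5)
  lo <- gliascope:::cpp_seeded_watershed(img, seeds, th_lo)
  hi <- gliascope:::cpp_seeded_watershed(img, seeds, th_hi)
  for (id in 1:2) expect_lte(sum(hi == id), sum(lo == id))
  # area filter monotonicity
  ph <- generate_microglia_phantom(phantom_params(n_cells = 5, image_shape = c(384, 384),
                                                  rng_seed = 9))
  n_loose <- n_labels(filter_cells(ph$labels, 300))
  n_strict <- n_labels(filter_cells(ph$labels, 1200))
  expect_lte(n_strict, n_loose)
})

test_that("the 900 px cell filter keeps only strictly larger cells", {
  m <- matrix(0L, 80, 80)
  m[1:29, 1:31] <- 1L; m[1, 1] <- 0L   # 899 px -> removed
  m[41:70, 41:71] <- 2L                # 930 px -> kept
  f1 <- filter_cells(label_map(m), 900)
  expect_equal(n_labels(f1), 1)
  expect_true(all(f1$labels[41:70, 41:71] == 1L))
  m2 <- matrix(0L, 80, 80)
  m2[1:30, 1:30] <- 1L                 # 900 px exactly -> removed ("larger than")
  m2[41:70, 41:71] <- 2L               # 930 px -> kept
  f2 <- filter_cells(label_map(m2), 900)
  expect_equal(n_labels(f2), 1)
  expect_true(all(f2$labels[41:70, 41:71] == 1L))
  # empty map stays empty; all-above-threshold map keeps its count
  expect_equal(n_labels(filter_cells(label_map(matrix(0L, 10, 10)), 900)), 0)
  expect_equal(n_labels(filter_cells(f2, 100)), 1)
})

test_that("full pipeline recovers phantom cells and returns tidy tables", {
  ph <- generate_microglia_phantom(phantom_params(rng_seed = 2))
  seg <- run_ihc_pipeline(ph$image)
  expect_s3_class(seg, "glia_segmentation")
  expect_lte(abs(n_labels(seg$labels) - 12), 1)
  expect_s3_class(tidy(seg), "tbl_df")
  expect_equal(nrow(tidy(seg)), n_labels(seg$labels))
  expect_equal(glance(seg)$n_cells, n_labels(seg$labels))
  # blank image gives zero cells and an empty table
  blank <- run_ihc_pipeline(matrix(255, 256, 256))
  expect_equal(n_labels(blank$labels), 0)
  expect_equal(nrow(blank$cells), 0)
})

test_that("cells whose somata are masked from the seeds stay background", {
  # sparse phantom: cells are isolated, so an unseeded cell cannot be reached
  # by flooding from a neighbor
  ph <- generate_microglia_phantom(phantom_params(n_cells = 6, rng_seed = 6))
  sp <- segmentation_params()
  img <- preprocess(ph$image, sp)
  th2 <- compute_watershed_threshold(img, sp$f2)
  seeds <- detect_somata(img, sp)
  # remove the seeds overlapping truth cells 1..3
  sd_m <- seeds$labels
  for (id in 1:3) {
    hit <- setdiff(unique(sd_m[ph$labels$labels == id]), 0L)
    sd_m[sd_m %in% hit] <- 0L
  }
  out <- filter_cells(seeded_watershed(img, label_map(sd_m), th2), sp$min_cell_area_px)
  expect_equal(n_labels(out), 3)
  for (id in 1:3) {
    truth_px <- ph$labels$labels == id
    expect_lt(mean(out$labels[truth_px] > 0), 0.05)
  }
})
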