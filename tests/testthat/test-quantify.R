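mock_detection <- function(labels, np_mask) {
  hsmad:::new_detection_map(labels, ifelse(np_mask, 1L, NA_integer_),
                            np_mask, "np", 1L, "test")
}

test_that("relative NP signal follows its defining ratio", {
  # 10 NP+ pixels with band signal 5 each, 1000 non-background pixels
  g <- wavelength_grid(800, 1000, 21)
  band <- band_window(833, 988)
  arr <- array(0, c(20, 50, 21))
  labels <- matrix(SEG_TISSUE, 20, 50)
  np <- matrix(FALSE, 20, 50)
  np[1, 1:10] <- TRUE
  labels[np] <- SEG_CANDIDATE
  for (i in 1:10) arr[1, i, ] <- 5
  cube <- hyper_cube(arr, g)
  det <- mock_detection(labels, np)
  expect_equal(relative_np_signal(cube, det, band), 50 / 1000 / 5)
  # empty NP+ set gives 0 by the empty-sum convention
  det0 <- mock_detection(labels, matrix(FALSE, 20, 50))
  expect_equal(relative_np_signal(cube, det0, band), 0)
  # invariant to global intensity scaling
  cube2 <- hyper_cube(arr * 123, g)
  expect_equal(relative_np_signal(cube2, det, band),
               relative_np_signal(cube, det, band))
  # background pixels shrink the denominator
  labels2 <- labels; labels2[20, ] <- SEG_BACKGROUND
  det2 <- mock_detection(labels2, np)
  expect_equal(relative_np_signal(cube, det2, band), 50 / 950 / 5)
  # all-background image is undefined
  labels3 <- labels; labels3[] <- SEG_BACKGROUND
  expect_error(relative_np_signal(cube, mock_detection(labels3, np * FALSE)),
               "undefined")
})

test_that("a single NP+ pixel collapses the ratio to 1 / N_tissue", {
  g <- wavelength_grid(800, 1000, 21)
  arr <- array(1, c(10, 10, 21))
  arr[3, 3, ] <- 400
  labels <- matrix(SEG_TISSUE, 10, 10)
  np <- matrix(FALSE, 10, 10); np[3, 3] <- TRUE
  labels[np] <- SEG_CANDIDATE
  expect_equal(relative_np_signal(hyper_cube(arr, g),
                                  mock_detection(labels, np)),
               1 / 100)
})

test_that("pixel coverage counts NP+ over non-background pixels per ROI", {
  labels <- matrix(SEG_TISSUE, 20, 20)
  labels[1:5, ] <- SEG_BACKGROUND
  np <- matrix(FALSE, 20, 20)
  roi <- matrix(0L, 20, 20)
  roi[6:15, 1:10] <- 1L   # 100 tissue pixels
  roi[16:20, 1:10] <- 2L  # 50 tissue pixels
  np[6, 1:3] <- TRUE      # 3 NP+ in ROI 1
  labels[np] <- SEG_CANDIDATE
  det <- mock_detection(labels, np)
  expect_equal(pixel_coverage(det, roi, 1L), 3 / 100)
  expect_equal(pixel_coverage(det, roi, 2L), 0)
  # fully NP+ ROI has coverage 1
  np2 <- np; np2[16:20, 1:10] <- TRUE
  labels2 <- labels; labels2[np2] <- SEG_CANDIDATE
  expect_equal(pixel_coverage(mock_detection(labels2, np2), roi, 2L), 1)
  # relabelling permutes outputs consistently
  roi_perm <- matrix(0L, 20, 20)
  roi_perm[roi == 1L] <- 2L; roi_perm[roi == 2L] <- 1L
  expect_equal(pixel_coverage(det, roi_perm, 2L),
               pixel_coverage(det, roi, 1L))
  # ROI entirely in background is undefined; missing label is an error
  roi_bg <- matrix(0L, 20, 20); roi_bg[1:2, 1:2] <- 7L
  expect_error(pixel_coverage(det, roi_bg, 7L), "undefined")
  expect_error(pixel_coverage(det, roi, 9L), "not present")
})

test_that("NP+ counts are additive over disjoint ROIs", {
  ph <- small_scene(seed = 61, size = 64)
  lib_grid <- truncate_to_cutoff(numeric(361), ph$cube$grid, 566)$grid
  cents <- rbind(normalize_max(gaussian_spectrum(600, 90, grid = lib_grid)),
                 normalize_max(lorentzian_spectrum(900, 30, grid = lib_grid)))
  lib <- assemble_library(cents, lib_grid, 566)
  det <- classify_nearest_centroid(ph$cube, ph$segmap, lib)
  roi <- matrix(1L, 64, 64); roi[, 33:64] <- 2L
  n1 <- sum(roi == 1L & det$np_mask)
  n2 <- sum(roi == 2L & det$np_mask)
  expect_equal(n1 + n2, sum(det$np_mask))
})

test_that("field-of-view aggregation gives mean, sample sd and sem", {
  ag <- aggregate_fovs(c(1, 2, 3, 4))
  expect_equal(ag$mean, 2.5)
  expect_equal(ag$sd, sd(c(1, 2, 3, 4)))
  expect_equal(round(ag$sem, 4), 0.6455)
  expect_equal(aggregate_fovs(rep(3, 5))$sem, 0)
  one <- aggregate_fovs(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sd) && is.na(one$sem))
})

test_that("relative signal grows near-linearly with planted particle count", {
  densities <- c(0.0005, 0.001, 0.002, 0.003, 0.004)
  res <- vapply(densities, function(d) {
    ph <- small_scene(seed = 62, size = 128, np_density = d,
                      aggregate_fraction = 0, edge_artifact_rate = 0)
    lib_grid <- truncate_to_cutoff(numeric(361), ph$cube$grid, 566)$grid
    cents <- rbind(normalize_max(gaussian_spectrum(540, 80, grid = lib_grid)),
                   normalize_max(gaussian_spectrum(650, 90, grid = lib_grid)),
                   normalize_max(lorentzian_spectrum(900, 30, grid = lib_grid)))
    lib <- assemble_library(cents, lib_grid, 566)
    det <- classify_nearest_centroid(ph$cube, ph$segmap, lib)
    c(signal = relative_np_signal(ph$cube, det),
      planted = sum(ph$truth$np_single))
  }, numeric(2))
  fit <- lm(res["signal", ] ~ res["planted", ])
  expect_gte(summary(fit)$r.squared, 0.99)
  expect_true(all(diff(res["signal", ]) >= 0))
})
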