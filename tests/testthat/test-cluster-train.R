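test_that("training pixel collection matches an independent preprocessing oracle", {
  ph <- small_scene(seed = 41, size = 64)
  tp <- collect_training_pixels(list(ph$cube), list(ph$segmap))
  n_cand <- sum(ph$segmap == SEG_CANDIDATE)
  expect_equal(nrow(tp$pixels), n_cand)
  expect_equal(max(abs(apply(tp$pixels, 1, max) - 1)), 0)
  # first candidate pixel in raster order, preprocessed independently
  cand <- which(t(unclass(ph$segmap)) == SEG_CANDIDATE)[1]
  w <- ncol(ph$segmap)
  r <- (cand - 1) %/% w + 1; cc <- (cand - 1) %% w + 1
  expect_equal(tp$pixels[1, ],
               preprocess_oracle(ph$cube$data[r, cc, ], ph$cube$grid))
  # all-tissue map is an empty-training error
  allt <- ph$segmap; allt[] <- SEG_TISSUE
  expect_error(collect_training_pixels(list(ph$cube), list(allt)), "empty")
})

test_that("k = 1 returns the normalized mean spectrum", {
  set.seed(42)
  px <- matrix(runif(60, 0.1, 1), 12, 5)
  px <- px / apply(px, 1, max)
  km <- train_kmeans(px, 1, seed = 3)
  expect_equal(as.numeric(km$centroids), normalize_max(colMeans(px)))
})

test_that("the k-means objective on 8 points equals the exhaustive 2-partition optimum", {
  set.seed(43)
  pts <- matrix(rnorm(16), 8, 2)
  km <- train_kmeans(pts, 2, seed = 1, n_restarts = 25)
  # brute force over all 2^7 - 1 bipartitions (fix point 1 in group A)
  best <- Inf
  for (mask in 0:(2^7 - 1)) {
    inA <- c(TRUE, as.logical(bitwAnd(mask, 2^(0:6))))
    if (all(inA)) next
    ssq <- function(m) if (nrow(m) == 0) 0 else
      sum(sweep(m, 2, colMeans(m))^2)
    best <- min(best, ssq(pts[inA, , drop = FALSE]) +
                      ssq(pts[!inA, , drop = FALSE]))
  }
  expect_equal(km$objective, best, tolerance = 1e-10)
})

test_that("training is deterministic given the seed and recovers planted templates", {
  g <- wavelength_grid(600, 1000, 101)
  narrow <- normalize_max(lorentzian_spectrum(900, 30, 1, grid = g))
  broad <- normalize_max(lorentzian_spectrum(800, 90, 1, grid = g))
  set.seed(44)
  mk <- function(tmpl, n) t(replicate(n, normalize_max(
    tmpl + rnorm(101, 0, 0.02))))
  px <- rbind(mk(narrow, 40), mk(broad, 40))
  km1 <- train_kmeans(px, 2, seed = 9)
  km2 <- train_kmeans(px, 2, seed = 9)
  expect_identical(km1$centroids, km2$centroids)
  # each planted template matched by one centroid, peak within 1 grid step
  peak <- function(v) g$values[which.max(v)]
  peaks <- sort(apply(km1$centroids, 1, peak))
  expect_lte(abs(peaks[1] - 800), 4 + 1e-9)
  expect_lte(abs(peaks[2] - 900), 4 + 1e-9)
  expect_error(train_kmeans(px[1:3, ], 4), "at least k")
})

test_that("library assembly selects the in-band centroid and serializes to JSON", {
  g <- wavelength_grid(566.6667, 1000, 261)
  cents <- rbind(
    normalize_max(gaussian_spectrum(580, 60, grid = g)),
    normalize_max(gaussian_spectrum(610, 60, grid = g)),
    normalize_max(gaussian_spectrum(650, 70, grid = g)),
    normalize_max(lorentzian_spectrum(900, 30, grid = g)))
  lib <- assemble_library(cents, g, 566)
  expect_equal(lib$np_index, 4L)
  expect_equal(lib$roles, c("stain", "stain", "stain", "np"))
  # a single centroid inside the band is selected even alone among two
  lib2 <- assemble_library(cents[c(1, 4), ], g, 566)
  expect_equal(lib2$np_index, 2L)
  # no centroid in band: explicit selection required
  expect_error(assemble_library(cents[1:3, ], g, 566), "np_index")
  # manual clusters are appended with their role
  ab <- normalize_max(lorentzian_spectrum(915, 90, grid = g))
  lib3 <- assemble_library(cents, g, 566,
                           manual = list(list(values = ab)))
  expect_equal(nrow(lib3$centroids), 5L)
  expect_equal(lib3$roles[5], "aberration")
  # JSON round trip is lossless
  path <- withr::local_tempfile(fileext = ".json")
  write_library(lib3, path)
  back <- read_library(path)
  expect_equal(back$centroids, lib3$centroids)
  expect_equal(back$roles, lib3$roles)
  expect_equal(back$np_index, lib3$np_index)
  expect_equal(back$grid$values, g$values)
})

test_that("ambiguous in-band centroids resolve to the larger band mean", {
  g <- wavelength_grid(566.6667, 1000, 261)
  cents <- rbind(
    normalize_max(lorentzian_spectrum(900, 30, grid = g)),
    normalize_max(lorentzian_spectrum(910, 90, grid = g)),
    normalize_max(gaussian_spectrum(600, 60, grid = g)))
  lib <- assemble_library(cents, g, 566)
  bm <- apply(cents[1:2, ], 1, band_mean, grid = g, band = np_band_default())
  expect_equal(lib$np_index, which.max(bm))
})

test_that("the aberration cluster averages falsely detected control spectra", {
  # controls: tissue-like scene with edge artifacts but no particles
  ph <- small_scene(seed = 45, size = 96, np_density = 0,
                    edge_artifact_rate = 0.3)
  # provisional library built from known templates: stains + particle
  tg <- truncate_to_cutoff(ph$truth$np_template, ph$cube$grid, 566)$grid
  cents <- rbind(
    normalize_max(gaussian_spectrum(540, 80, grid = tg)),
    normalize_max(gaussian_spectrum(650, 90, grid = tg)),
    preprocess_oracle(ph$truth$np_template + 1e-9, ph$cube$grid))
  lib <- assemble_library(cents, tg, 566)
  ab <- build_aberration_cluster(list(ph$cube), list(ph$segmap), lib)
  expect_false(is.null(ab))  # broad-edge controls must produce false positives
  expect_equal(max(ab), 1)
  # artifact surrogate peaks near the planted edge template, and broader
  g <- truncate_to_cutoff(ph$truth$edge_template, ph$cube$grid, 566)
  expect_lte(abs(g$grid$values[which.max(ab)] -
                 g$grid$values[which.max(g$values)]), 10)
  fwhm <- function(v, grid) {
    above <- grid$values[v >= 0.5 * max(v)]
    max(above) - min(above)
  }
  np_t <- truncate_to_cutoff(ph$truth$np_template, ph$cube$grid, 566)
  expect_gt(fwhm(ab, g$grid), fwhm(np_t$values, np_t$grid))
})

test_that("identical false positives average to themselves, two to their midpoint", {
  # direct checks of the averaging rule on constructed spectra
  v1 <- normalize_max(lorentzian_spectrum(915, 90, grid = default_grid()))
  expect_equal(normalize_max(colMeans(rbind(v1, v1))), v1)
  v2 <- normalize_max(lorentzian_spectrum(870, 70, grid = default_grid()))
  expect_equal(normalize_max(colMeans(rbind(v1, v2))),
               normalize_max((v1 + v2) / 2))
})

test_that("on pure-particle phantoms the learned NP centroid matches its template", {
  um <- unmixing_benchmark(seed = 301, size = 128, n_particles = 120)
  expect_gte(um$cos_narrow, 0.98)
  expect_gte(um$cos_broad, 0.98)
})
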