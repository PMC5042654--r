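#' Field-of-view side length from pixel count and sampling pitch
#'
#' At 40x the instrument samples 509 x 512 pixels at 410 x 408 nm, i.e. a
#' ~209 x 209 um field of view.
#'
#' @param n_pixels Pixels along the axis.
#' @param pitch_nm Sampling pitch (nm/pixel).
#' @return Side length in micrometres.
#' @export
fov_side_um <- function(n_pixels, pitch_nm) n_pixels * pitch_nm / 1000

#' End-to-end phantom detection benchmark
#'
#' Runs the complete workflow on synthetic scenes: train the spectral
#' library by k-means on `train_seeds` phantoms, learn the
#' chromatic-aberration cluster from particle-free `control_seeds`
#' phantoms, then classify the `test_seed` phantom with the aberration
#' cluster disabled and enabled. Sensitivity is scored on single-particle
#' centre pixels; specificity on tissue and edge-artifact pixels (PSF halo
#' pixels, which carry real particle light, are excluded from the negative
#' set); the edge false-positive rate is the fraction of planted
#' edge-artifact pixels called NP+.
#'
#' @param train_seeds Seeds of the training phantoms.
#' @param test_seed Seed of the held-out test phantom.
#' @param control_seeds Seeds of particle-free control phantoms.
#' @param size Phantom side length in pixels.
#' @param k Number of k-means clusters.
#' @param preset Phantom preset name.
#' @param seed k-means training seed.
#' @param ... Further [phantom_config()] overrides applied to every scene.
#' @return List: `sensitivity`, `specificity`, `edge_fp_enabled`,
#'   `edge_fp_disabled`, `edge_fp_reduction`, `library`, `relative_signal`.
#' @export
phantom_benchmark <- function(train_seeds = 1:3, test_seed = 4,
                              control_seeds = 5, size = 256L, k = 4L,
                              preset = "lgnr", seed = 1L, ...) {
  ppc <- preprocess_config()
  gen <- function(s, ...) {
    ph <- generate_phantom(phantom_preset(preset, seed = s, height = size,
                                          width = size, ...))
    ph$cube <- vignette_correct(ph$cube)
    img <- mean_intensity(ph$cube)
    ph$segmap <- segment(img, adaptive_thresholds(img))
    ph
  }
  train <- lapply(train_seeds, gen, ...)
  tp <- collect_training_pixels(lapply(train, `[[`, "cube"),
                                lapply(train, `[[`, "segmap"), ppc)
  km <- train_kmeans(tp$pixels, k, seed = seed)
  lib0 <- assemble_library(km$centroids, tp$grid, ppc$cutoff_nm,
                           k = k, seed = seed)
  rm(train)

  controls <- lapply(control_seeds, gen, np_density = 0, ...)
  ab <- build_aberration_cluster(lapply(controls, `[[`, "cube"),
                                 lapply(controls, `[[`, "segmap"),
                                 lib0, ppc)
  rm(controls)
  lib1 <- if (is.null(ab)) lib0 else
    assemble_library(km$centroids, tp$grid, ppc$cutoff_nm,
                     manual = list(list(values = ab)), k = k, seed = seed)

  test <- gen(test_seed, ...)
  tr <- test$truth
  score <- function(lib) {
    det <- classify_nearest_centroid(test$cube, test$segmap, lib, ppc)
    neg <- (tr$tissue | tr$edge_artifact) &
      !tr$np_single & !tr$np_aggregate & !tr$np_halo
    list(det = det,
         sensitivity = sum(det$np_mask & tr$np_single) / sum(tr$np_single),
         specificity = sum(!det$np_mask & neg) / sum(neg),
         edge_fp = if (sum(tr$edge_artifact) > 0)
           sum(det$np_mask & tr$edge_artifact) / sum(tr$edge_artifact)
         else NA_real_)
  }
  s0 <- score(lib0)
  s1 <- score(lib1)
  list(sensitivity = s1$sensitivity, specificity = s1$specificity,
       edge_fp_enabled = s1$edge_fp, edge_fp_disabled = s0$edge_fp,
       edge_fp_reduction = if (is.finite(s0$edge_fp) && s0$edge_fp > 0)
         1 - s1$edge_fp / s0$edge_fp else NA_real_,
       sensitivity_disabled = s0$sensitivity,
       specificity_disabled = s0$specificity,
       library = lib1,
       relative_signal = relative_np_signal(test$cube, s1$det))
}

#' Two-template unmixing benchmark on pure-particle phantoms
#'
#' Trains 2 k-means clusters on a mixture phantom (narrow ~900 nm and broad
#' ~800 nm species) and cross-classifies pure single-species phantoms.
#' Pure-particle slides have sparse intensity histograms, so the adaptive
#' thresholds use a 1-unit resampling step here.
#'
#' @param seed Base phantom seed (mixture uses `seed`, pure slides
#'   `seed + 1`, `seed + 2`).
#' @param size Phantom side length (pixels).
#' @param n_particles Particles per species.
#' @return List: `cos_narrow`, `cos_broad` (cosine of each learned centroid
#'   with its planted template after identical preprocessing), `accuracy`
#'   (overall cross-classification accuracy on pure slides), `library`.
#' @export
unmixing_benchmark <- function(seed = 201L, size = 160L, n_particles = 150L) {
  ppc <- preprocess_config()
  tpar <- threshold_params(resample_step = 1)
  gen <- function(s, n1, n2) {
    ph <- generate_phantom(phantom_preset("mixture", seed = s, height = size,
                                          width = size, np_count = n1,
                                          np2_count = n2))
    ph$cube <- vignette_correct(ph$cube)
    img <- mean_intensity(ph$cube)
    ph$segmap <- segment(img, adaptive_thresholds(img, tpar))
    ph
  }
  mix <- gen(seed, n_particles, n_particles)
  tp <- collect_training_pixels(list(mix$cube), list(mix$segmap), ppc)
  km <- train_kmeans(tp$pixels, 2L, seed = 1L)
  prep1 <- function(v) preprocess_spectra(matrix(v + 1e-9, 1),
                                          mix$cube$grid, ppc)$spectra[1, ]
  t_narrow <- prep1(mix$truth$np_template)
  t_broad <- prep1(mix$truth$np2_template)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cs <- vapply(1:2, function(i)
    c(cosv(km$centroids[i, ], t_narrow), cosv(km$centroids[i, ], t_broad)),
    numeric(2))
  i_narrow <- which.max(cs[1, ])
  lib <- assemble_library(km$centroids, tp$grid, ppc$cutoff_nm,
                          np_index = i_narrow, k = 2L, seed = 1L)
  hits <- 0L; total <- 0L
  for (sp in 1:2) {
    pure <- gen(seed + sp, if (sp == 1) n_particles else 0L,
                if (sp == 2) n_particles else 0L)
    det <- classify_nearest_centroid(pure$cube, pure$segmap, lib, ppc)
    cl <- det$cluster[!is.na(det$cluster)]
    want <- if (sp == 1) i_narrow else 3L - i_narrow
    hits <- hits + sum(cl == want); total <- total + length(cl)
  }
  list(cos_narrow = cs[1, i_narrow], cos_broad = cs[2, 3 - i_narrow],
       accuracy = hits / total, library = lib)
}
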