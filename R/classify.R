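#' Per-pixel detection map
#'
#' Carries the segmentation labels, the per-candidate cluster assignment
#' (NA outside candidate pixels) and the derived nanoparticle-positive mask.
#'
#' @name detection_map
NULL

new_detection_map <- function(labels, cluster, np_mask, roles, np_index,
                              method, n_excluded = 0L) {
  structure(list(labels = labels, cluster = cluster, np_mask = np_mask,
                 roles = roles, np_index = np_index, method = method,
                 n_excluded = n_excluded),
            class = "detection_map")
}

#' @export
print.detection_map <- function(x, ...) {
  cat(sprintf("<detection_map> %d x %d, method %s: %d NP+ of %d candidates\n",
              nrow(x$labels), ncol(x$labels), x$method,
              sum(x$np_mask), sum(x$labels == SEG_CANDIDATE)))
  invisible(x)
}

#' Per-cluster pixel counts of a detection map
#' @param detection A `detection_map`.
#' @return data.frame with `cluster`, `role`, `n_pixels`. Aberration-cluster
#'   pixels are nanoparticle-negative but tracked separately here.
#' @export
detection_counts <- function(detection) {
  stopifnot(inherits(detection, "detection_map"))
  k <- length(detection$roles)
  data.frame(cluster = seq_len(k), role = detection$roles,
             n_pixels = vapply(seq_len(k), function(i)
               sum(detection$cluster == i, na.rm = TRUE), integer(1)))
}

#' Nearest-centroid classification of candidate pixels
#'
#' Each candidate pixel is preprocessed identically to training (truncate,
#' Savitzky-Golay, max-normalize) and assigned to the library centroid at
#' minimum Euclidean distance; ties go to the lowest cluster index. A pixel
#' is nanoparticle-positive iff its assigned cluster is the library's
#' `np_index`. Background and tissue labels pass through unchanged.
#'
#' @param cube A [hyper_cube()]; its truncated grid must match the library.
#' @param segmap Segmentation map from [segment()].
#' @param library A [spectral_library()].
#' @param config [preprocess_config()]; `cutoff_nm` must equal the
#'   library's.
#' @return A `detection_map`.
#' @export
classify_nearest_centroid <- function(cube, segmap, library,
                                      config = preprocess_config()) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(library, "spectral_library"))
  if (abs(config$cutoff_nm - library$cutoff_nm) > 1e-9)
    stop("preprocessing cutoff differs from the library's", call. = FALSE)
  d <- dim(cube$data)
  cluster <- matrix(NA_integer_, d[1], d[2])
  np_mask <- matrix(FALSE, d[1], d[2])
  cs <- candidate_spectra(cube, segmap)
  n_excl <- 0L
  if (nrow(cs$spectra) > 0L) {
    pp <- preprocess_spectra(cs$spectra, cube$grid, config)
    if (!grids_equal(pp$grid, library$grid))
      stop("cube grid after truncation does not match library grid",
           call. = FALSE)
    ok <- !pp$degenerate
    n_excl <- sum(!ok)
    if (any(ok)) {
      x <- pp$spectra[ok, , drop = FALSE]
      cent <- library$centroids
      # squared Euclidean distances via the expansion trick
      d2 <- outer(rowSums(x^2), rowSums(cent^2), `+`) - 2 * x %*% t(cent)
      assign <- max.col(-d2, ties.method = "first")
      # raster index -> (row, col): fill through the transposed matrix
      tc <- t(cluster)
      tc[cs$raster_idx[ok]] <- assign
      cluster <- t(tc)
      np_mask <- !is.na(cluster) & cluster == library$np_index
    }
  }
  new_detection_map(segmap_matrix(segmap), cluster, np_mask,
                    library$roles, library$np_index, "nearest_centroid",
                    n_excl)
}

segmap_matrix <- function(segmap) {
  m <- unclass(segmap)
  attr(m, "bg_threshold") <- NULL
  attr(m, "candidate_threshold") <- NULL
  m
}

#' Spectral Angle Mapper (SAM) baseline classification
#'
#' A candidate pixel is nanoparticle-positive iff the angle between its
#' preprocessed spectrum and the reference spectrum is at most
#' `angle_tol_rad`. Zero-norm spectra cannot subtend an angle and are
#' excluded (counted in `n_excluded`).
#'
#' @param cube A [hyper_cube()].
#' @param segmap Segmentation map.
#' @param reference Reference spectrum on the truncated grid (same
#'   preprocessing as the pixels).
#' @param angle_tol_rad Angular tolerance in radians, in (0, pi/2).
#' @param config [preprocess_config()].
#' @return A `detection_map` with a single pseudo-cluster (`np`).
#' @export
classify_sam <- function(cube, segmap, reference, angle_tol_rad,
                         config = preprocess_config()) {
  stopifnot(inherits(cube, "hyper_cube"))
  if (!is.finite(angle_tol_rad) || angle_tol_rad <= 0 || angle_tol_rad >= pi / 2)
    stop("angle_tol_rad must lie in (0, pi/2)", call. = FALSE)
  d <- dim(cube$data)
  cluster <- matrix(NA_integer_, d[1], d[2])
  np_mask <- matrix(FALSE, d[1], d[2])
  cs <- candidate_spectra(cube, segmap)
  n_excl <- 0L
  if (nrow(cs$spectra) > 0L) {
    pp <- preprocess_spectra(cs$spectra, cube$grid, config)
    if (length(reference) != pp$grid$n_samples)
      stop("reference length does not match truncated grid", call. = FALSE)
    rn <- sqrt(sum(reference^2))
    if (rn <= 0) stop("reference spectrum has zero norm", call. = FALSE)
    xn <- sqrt(rowSums(pp$spectra^2))
    ok <- !pp$degenerate & is.finite(xn) & xn > 0
    n_excl <- sum(!ok)
    if (n_excl > 0L)
      warning(n_excl, " zero-norm candidate spectra excluded from SAM",
              call. = FALSE)
    cosang <- pmin(1, pmax(-1,
      (pp$spectra %*% reference)[, 1] / (xn * rn)))
    hit <- ok & acos(cosang) <= angle_tol_rad
    tc <- t(cluster)
    tc[cs$raster_idx[hit]] <- 1L
    cluster <- t(tc)
    np_mask <- !is.na(cluster)
  }
  new_detection_map(segmap_matrix(segmap), cluster, np_mask,
                    "np", 1L, "sam", n_excl)
}
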