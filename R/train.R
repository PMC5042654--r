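#' Spectral preprocessing configuration
#'
#' The identical per-pixel preprocessing chain used for both training and
#' classification: truncate below the wavelength cutoff, Savitzky-Golay
#' smooth, then max-normalize.
#'
#' @param cutoff_nm Truncation cutoff (default 566 nm; channels below are
#'   dominated by detector noise).
#' @param sg_window Savitzky-Golay window length in samples (odd,
#'   default 11).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(cutoff_nm = 566, sg_window = 11L, sg_order = 3L) {
  structure(list(cutoff_nm = cutoff_nm, sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order)),
            class = "preprocess_config")
}

#' Preprocess a matrix of pixel spectra
#'
#' Applies truncate -> Savitzky-Golay smooth -> max-normalize to each row.
#' Rows whose post-smoothing maximum is not positive cannot be normalized
#' and are flagged in `degenerate`.
#'
#' @param spectra Pixels x bands matrix on `grid`.
#' @param grid [wavelength_grid()] matching the columns.
#' @param config A [preprocess_config()].
#' @return List: `spectra` (pixels x retained-bands, rows max = 1, degenerate
#'   rows `NA`), `grid` (truncated grid), `degenerate` (logical vector).
#' @export
preprocess_spectra <- function(spectra, grid, config = preprocess_config()) {
  stopifnot(is.matrix(spectra), inherits(grid, "wavelength_grid"),
            inherits(config, "preprocess_config"))
  if (ncol(spectra) != grid$n_samples)
    stop("spectra columns do not match grid", call. = FALSE)
  keep <- truncate_indices(grid, config$cutoff_nm)
  sub <- grid$values[keep]
  g <- wavelength_grid(sub[1L], sub[length(sub)], length(sub))
  x <- spectra[, keep, drop = FALSE]
  sm <- t(apply(x, 1L, function(row)
    signal::sgolayfilt(row, p = config$sg_order, n = config$sg_window)))
  if (nrow(x) == 1L) sm <- matrix(sm, nrow = 1L)
  mx <- apply(sm, 1L, max)
  degenerate <- !is.finite(mx) | mx <= 0
  out <- sm / mx
  out[degenerate, ] <- NA_real_
  list(spectra = out, grid = g, degenerate = degenerate)
}

# candidate pixels of one cube in raster order, raw spectra
candidate_spectra <- function(cube, segmap) {
  stopifnot(inherits(cube, "hyper_cube"))
  d <- dim(cube$data)
  if (!all(dim(segmap) == d[1:2]))
    stop("segmentation map does not match cube", call. = FALSE)
  idx <- which(t(segmap == SEG_CANDIDATE))  # t() => raster (row-major) order
  m <- cube_to_matrix(cube)
  list(spectra = m[idx, , drop = FALSE], raster_idx = idx)
}

#' Collect preprocessed candidate-pixel spectra for training
#'
#' Rows are exactly the candidate-labelled pixels of each image, in raster
#' order, preprocessed by [preprocess_spectra()]. Degenerate (unnormalizable)
#' rows are dropped.
#'
#' @param cubes List of [hyper_cube()] sharing one grid.
#' @param segmaps List of matching segmentation maps.
#' @param config A [preprocess_config()].
#' @return List: `pixels` (matrix, each row max = 1), `grid` (truncated
#'   grid), `image_id` (integer per row).
#' @export
collect_training_pixels <- function(cubes, segmaps,
                                    config = preprocess_config()) {
  stopifnot(length(cubes) == length(segmaps), length(cubes) >= 1L)
  g0 <- cubes[[1]]$grid
  rows <- list(); ids <- integer(0)
  for (i in seq_along(cubes)) {
    if (!grids_equal(cubes[[i]]$grid, g0))
      stop("training cubes must share one wavelength grid", call. = FALSE)
    cs <- candidate_spectra(cubes[[i]], segmaps[[i]])
    if (nrow(cs$spectra) == 0L) next
    pp <- preprocess_spectra(cs$spectra, g0, config)
    keep <- !pp$degenerate
    rows[[length(rows) + 1L]] <- pp$spectra[keep, , drop = FALSE]
    ids <- c(ids, rep(i, sum(keep)))
    grid_trunc <- pp$grid
  }
  if (length(rows) == 0L)
    stop("empty training set: no candidate pixels in any image",
         call. = FALSE)
  list(pixels = do.call(rbind, rows), grid = grid_trunc, image_id = ids)
}

# run expr with a fixed RNG state, restoring the caller's state after
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' k-means training of spectral cluster centroids
#'
#' Standard k-means (within-cluster squared Euclidean distance) with
#' multiple random restarts; deterministic given `seed`. Centroids are
#' re-normalized to unit maximum after averaging so they live on the same
#' scale as preprocessed pixels.
#'
#' @param pixels Preprocessed pixel matrix (rows max = 1).
#' @param k Number of clusters; `nrow(pixels) >= k`.
#' @param seed RNG seed (restarts are reproducible bit-for-bit).
#' @param n_restarts Random restarts (default 10); the best objective wins.
#' @param iter_max Maximum Lloyd/Hartigan-Wong iterations.
#' @return List: `centroids` (k x bands, rows max = 1), `objective` (total
#'   within-cluster sum of squares, computed on the unnormalized centroids),
#'   `cluster` (assignment per input row), `sizes`.
#' @export
train_kmeans <- function(pixels, k, seed = 1L, n_restarts = 10L,
                         iter_max = 200L) {
  stopifnot(is.matrix(pixels))
  if (nrow(pixels) < k)
    stop("need at least k pixel rows to train k clusters", call. = FALSE)
  km <- with_seed(seed,
    stats::kmeans(pixels, centers = k, nstart = n_restarts,
                  iter.max = iter_max))
  cent <- km$centers
  cent <- cent / apply(cent, 1L, max)
  list(centroids = unname(cent), objective = km$tot.withinss,
       cluster = km$cluster, sizes = km$size)
}

#' Spectral cluster library
#'
#' Ordered set of max-normalized centroid spectra on the truncated grid,
#' with per-centroid role tags and the index of the nanoparticle cluster.
#'
#' @param centroids k x bands matrix, every row max-normalized.
#' @param grid Truncated [wavelength_grid()] matching the columns.
#' @param roles Character vector per centroid, values in
#'   `c("stain", "intermediate", "np", "aberration")`.
#' @param np_index Index of the nanoparticle centroid.
#' @param cutoff_nm Truncation cutoff the library was trained with.
#' @param k Number of k-means clusters used.
#' @param seed Training seed.
#' @param training_ids Optional identifiers of the training images.
#' @return A `spectral_library` object.
#' @export
spectral_library <- function(centroids, grid, roles, np_index, cutoff_nm,
                             k = nrow(centroids), seed = NA_integer_,
                             training_ids = NULL) {
  stopifnot(is.matrix(centroids), inherits(grid, "wavelength_grid"))
  if (nrow(centroids) < 2L)
    stop("a library needs at least 2 centroids", call. = FALSE)
  if (ncol(centroids) != grid$n_samples)
    stop("centroid length does not match grid", call. = FALSE)
  if (length(roles) != nrow(centroids))
    stop("one role per centroid required", call. = FALSE)
  bad <- setdiff(roles, c("stain", "intermediate", "np", "aberration"))
  if (length(bad))
    stop("unknown roles: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!np_index %in% seq_len(nrow(centroids)) || roles[np_index] != "np")
    stop("np_index must point at a centroid with role 'np'", call. = FALSE)
  if (max(abs(apply(centroids, 1L, max) - 1)) > 1e-8)
    stop("all centroids must be max-normalized", call. = FALSE)
  structure(list(centroids = unname(centroids), grid = grid,
                 roles = roles, np_index = as.integer(np_index),
                 cutoff_nm = cutoff_nm, k = as.integer(k),
                 seed = seed, training_ids = training_ids),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d centroids (%s), np_index = %d, cutoff %g nm\n",
              nrow(x$centroids), paste(x$roles, collapse = ", "),
              x$np_index, x$cutoff_nm))
  invisible(x)
}

#' Assemble a spectral library from k-means centroids and manual clusters
#'
#' The nanoparticle centroid is auto-selected as the k-means centroid whose
#' argmax wavelength falls inside `np_band` (ties broken by larger band
#' mean); remaining k-means centroids are tagged `"stain"`. Manual clusters
#' (typically the chromatic-aberration centroid) are appended after.
#'
#' @param centroids k-means centroid matrix on the truncated grid.
#' @param grid Truncated [wavelength_grid()].
#' @param cutoff_nm Truncation cutoff used for training.
#' @param np_band [band_window()] locating the plasmon resonance (default
#'   833-988 nm).
#' @param manual Optional list of manual clusters, each a list with `values`
#'   (max-normalized) and `role` (default `"aberration"`).
#' @param np_index Explicit nanoparticle centroid index; overrides
#'   auto-selection (required when no centroid peaks inside `np_band`).
#' @param k,seed,training_ids Metadata passed to [spectral_library()].
#' @return A [spectral_library()].
#' @export
assemble_library <- function(centroids, grid, cutoff_nm,
                             np_band = np_band_default(), manual = NULL,
                             np_index = NULL, k = nrow(centroids),
                             seed = NA_integer_, training_ids = NULL) {
  stopifnot(is.matrix(centroids), nrow(centroids) >= 1L)
  if (is.null(np_index)) {
    peaks <- grid$values[apply(centroids, 1L, which.max)]
    inside <- which(peaks >= np_band$lo_nm & peaks <= np_band$hi_nm)
    if (length(inside) == 0L)
      stop("no centroid peaks inside the nanoparticle band; ",
           "set np_index explicitly", call. = FALSE)
    if (length(inside) > 1L) {
      bm <- vapply(inside, function(i)
        band_mean(centroids[i, ], grid, np_band), numeric(1))
      inside <- inside[which.max(bm)]
    }
    np_index <- inside
  }
  roles <- rep("stain", nrow(centroids))
  roles[np_index] <- "np"
  all_cent <- centroids
  for (mc in manual) {
    v <- as.numeric(mc$values)
    if (length(v) != grid$n_samples)
      stop("manual cluster length does not match grid", call. = FALSE)
    all_cent <- rbind(all_cent, v)
    roles <- c(roles, if (is.null(mc$role)) "aberration" else mc$role)
  }
  spectral_library(all_cent, grid, roles, np_index, cutoff_nm,
                   k = k, seed = seed, training_ids = training_ids)
}

#' Learn the chromatic-aberration cluster from negative controls
#'
#' Classifies nanoparticle-free control images with a provisional library
#' and averages the preprocessed spectra of pixels falsely assigned to the
#' nanoparticle cluster; the max-normalized mean is the aberration centroid.
#'
#' @param control_cubes List of [hyper_cube()] known to contain no
#'   nanoparticles.
#' @param control_segmaps Matching segmentation maps.
#' @param library Provisional [spectral_library()] (k-means clusters only).
#' @param config [preprocess_config()] used for the library.
#' @return Max-normalized aberration spectrum, or `NULL` when the controls
#'   produce no false positives (library left unchanged by the caller).
#' @export
build_aberration_cluster <- function(control_cubes, control_segmaps, library,
                                     config = preprocess_config()) {
  stopifnot(inherits(library, "spectral_library"))
  fp <- list()
  for (i in seq_along(control_cubes)) {
    det <- classify_nearest_centroid(control_cubes[[i]], control_segmaps[[i]],
                                     library, config)
    hit <- which(t(det$np_mask))  # raster order, matches candidate_spectra
    if (length(hit) == 0L) next
    cs <- candidate_spectra(control_cubes[[i]], control_segmaps[[i]])
    sel <- cs$raster_idx %in% hit
    pp <- preprocess_spectra(cs$spectra[sel, , drop = FALSE],
                             control_cubes[[i]]$grid, config)
    fp[[length(fp) + 1L]] <- pp$spectra[!pp$degenerate, , drop = FALSE]
  }
  if (length(fp) == 0L) return(NULL)
  m <- do.call(rbind, fp)
  if (nrow(m) == 0L) return(NULL)
  structure(normalize_max(colMeans(m)), role = "aberration")
}

#' Write a spectral library to JSON
#' @param library A [spectral_library()].
#' @param path Output path.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "spectral_library"))
  g <- library$grid
  jsonlite::write_json(
    list(cutoff_nm = library$cutoff_nm,
         grid = list(start = g$start_nm, end = g$end_nm, n = g$n_samples),
         centroids = lapply(seq_len(nrow(library$centroids)), function(i)
           list(role = library$roles[i],
                values = library$centroids[i, ])),
         np_index = library$np_index, k = library$k, seed = library$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral library written by [write_library()]
#' @param path JSON path.
#' @return A [spectral_library()].
#' @export
read_library <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cent <- do.call(rbind, lapply(x$centroids, function(ci)
    as.numeric(unlist(ci$values))))
  roles <- vapply(x$centroids, function(ci) ci$role, character(1))
  spectral_library(cent,
                   wavelength_grid(x$grid$start, x$grid$end, x$grid$n),
                   roles, x$np_index, x$cutoff_nm, k = x$k,
                   seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}
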