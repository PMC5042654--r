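#' Segmentation label codes
#'
#' Pixels are partitioned into background (0), tissue (1) and candidate
#' nanoparticle / bright scatterer (2).
#' @export
SEG_BACKGROUND <- 0L
#' @rdname SEG_BACKGROUND
#' @export
SEG_TISSUE <- 1L
#' @rdname SEG_BACKGROUND
#' @export
SEG_CANDIDATE <- 2L

#' Per-pixel mean intensity image
#'
#' Arithmetic mean over all bands of each pixel's spectrum; the working
#' image for adaptive segmentation.
#'
#' @param cube A [hyper_cube()].
#' @return H x W numeric matrix.
#' @export
mean_intensity <- function(cube) {
  stopifnot(inherits(cube, "hyper_cube"))
  rowMeans(cube$data, dims = 2L)
}

#' Cosine-fourth vignetting model
#'
#' Radial illumination falloff proportional to cos^4(theta) with
#' theta = atan(R / d), R the physical distance (mm) of a pixel from the
#' image centre computed from the per-axis pixel pitch.
#'
#' @param d_mm Falloff distance (mm); the instrument fit gives 2 mm.
#' @param pitch_nm Per-axis sampling pitch in nm, `c(row, col)`; the 40x
#'   objective samples at 410 x 408 nm. A scalar is recycled to both axes.
#' @param center Optional fractional `(row, col)` centre; defaults to the
#'   geometric image centre.
#' @return A `vignette_model` object.
#' @export
vignette_model <- function(d_mm = 2, pitch_nm = c(410, 408), center = NULL) {
  if (!is.finite(d_mm) || d_mm <= 0) stop("d_mm must be > 0", call. = FALSE)
  pitch_nm <- rep_len(as.numeric(pitch_nm), 2L)
  if (any(!is.finite(pitch_nm)) || any(pitch_nm <= 0))
    stop("pixel pitch must be > 0", call. = FALSE)
  structure(list(d_mm = d_mm, pitch_nm = pitch_nm, center = center),
            class = "vignette_model")
}

#' Vignetting attenuation factors for an image size
#'
#' @param model A [vignette_model()].
#' @param dims `c(height, width)` in pixels.
#' @return Matrix of cos^4(atan(R/d)) factors in (0, 1]; 1 at the centre.
#' @export
vignette_factors <- function(model, dims) {
  stopifnot(inherits(model, "vignette_model"), length(dims) >= 2L)
  h <- dims[1]; w <- dims[2]
  ctr <- if (is.null(model$center)) c((h + 1) / 2, (w + 1) / 2) else model$center
  # physical offsets in mm (pitch is nm/px)
  dr <- (seq_len(h) - ctr[1]) * model$pitch_nm[1] * 1e-6
  dc <- (seq_len(w) - ctr[2]) * model$pitch_nm[2] * 1e-6
  R <- sqrt(outer(dr^2, dc^2, `+`))
  cos(atan(R / model$d_mm))^4
}

#' Correct vignetting on a cube or intensity image
#'
#' Divides every value by the modelled cos^4 falloff, so the correction
#' factor is >= 1 everywhere and exactly 1 at the centre.
#'
#' @param x A [hyper_cube()] or an H x W intensity matrix.
#' @param model A [vignette_model()].
#' @return Object of the same type as `x`, corrected.
#' @export
vignette_correct <- function(x, model = vignette_model()) {
  if (inherits(x, "hyper_cube")) {
    f <- vignette_factors(model, dim(x$data))
    hyper_cube(x$data / as.vector(f), x$grid)
  } else if (is.matrix(x)) {
    x / vignette_factors(model, dim(x))
  } else {
    stop("x must be a hyper_cube or a matrix", call. = FALSE)
  }
}

#' Apply vignetting attenuation (inverse of the correction)
#' @inheritParams vignette_correct
#' @return Attenuated object, same type as `x`.
#' @export
vignette_apply <- function(x, model = vignette_model()) {
  if (inherits(x, "hyper_cube")) {
    f <- vignette_factors(model, dim(x$data))
    hyper_cube(x$data * as.vector(f), x$grid)
  } else {
    x * vignette_factors(model, dim(x))
  }
}

#' Adaptive threshold parameters
#'
#' @param n_bins Histogram bins over `[0, max]` (default 510).
#' @param resample_step Resampling step of the histogram, in intensity
#'   units (default 5); the raw histogram is linearly re-interpolated on
#'   this coarser lattice before the minimum search.
#' @param alpha Background multiplier (>= 1, default 1.05): scales the
#'   first-minimum intensity into the background threshold.
#' @param beta Tissue-peak multiplier (>= 1, default 1.5): scales the
#'   dominant tissue-mode intensity into the candidate threshold.
#' @return A `threshold_params` object.
#' @export
threshold_params <- function(n_bins = 510L, resample_step = 5,
                             alpha = 1.05, beta = 1.5) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 10L) stop("n_bins must be >= 10", call. = FALSE)
  if (resample_step <= 0) stop("resample_step must be > 0", call. = FALSE)
  if (alpha < 1 || beta < 1) stop("alpha and beta must be >= 1", call. = FALSE)
  structure(list(n_bins = n_bins, resample_step = resample_step,
                 alpha = alpha, beta = beta), class = "threshold_params")
}

#' Adaptive background / candidate thresholds from the intensity histogram
#'
#' The histogram of the (vignette-corrected) mean-intensity image is
#' computed with `n_bins` bins over `[0, max]`, re-interpolated every
#' `resample_step` intensity units, and scanned upward: the first local
#' minimum after the initial (background) peak, scaled by `alpha`, gives
#' the background threshold; the highest remaining peak above it
#' ("peakHist", the tissue mode), scaled by `beta`, gives the candidate
#' threshold.
#'
#' @param img Intensity image (matrix), non-constant.
#' @param params A [threshold_params()].
#' @return List with `bg_threshold`, `candidate_threshold`, `min_hist`
#'   (first-minimum intensity), `peak_hist` (tissue-mode intensity) and the
#'   resampled `histogram` (data.frame `intensity`, `count`).
#' @export
adaptive_thresholds <- function(img, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  v <- as.vector(img)
  if (!all(is.finite(v)) || any(v < 0))
    stop("intensity image must be finite and nonnegative", call. = FALSE)
  mx <- max(v)
  if (mx <= min(v))
    stop("segmentation failure: constant intensity image", call. = FALSE)
  br <- seq(0, mx, length.out = params$n_bins + 1L)
  h <- graphics::hist(v, breaks = br, plot = FALSE)
  xs <- seq(0, mx, by = params$resample_step)
  if (length(xs) < 4L)
    stop("segmentation failure: resample_step too coarse for intensity range",
         call. = FALSE)
  hr <- stats::approx(h$mids, h$counts, xout = xs, rule = 2)$y
  n <- length(hr)
  # first local maximum scanning upward from 0
  pk <- NA_integer_
  for (i in seq_len(n - 1L)) {
    if (hr[i] >= hr[i + 1L]) { pk <- i; break }
  }
  hist_df <- data.frame(intensity = xs, count = hr)
  fail <- function(msg) {
    e <- simpleError(paste0("segmentation failure: ", msg))
    e$histogram <- hist_df
    stop(e)
  }
  if (is.na(pk)) fail("monotone histogram, no background peak")
  # first minimum: descent (or plateau) ends where counts strictly rise again
  mn <- NA_integer_
  if (pk < n - 1L) {
    for (i in (pk):(n - 1L)) {
      if (hr[i + 1L] > hr[i]) { mn <- i; break }
    }
  }
  if (is.na(mn)) fail("no local minimum after background peak")
  min_hist <- xs[mn]
  bg <- min_hist * params$alpha
  above <- which(xs > bg)
  if (length(above) == 0L) fail("no histogram mass above background threshold")
  peak_hist <- xs[above][which.max(hr[above])]
  cand <- peak_hist * params$beta
  if (cand <= bg) fail("candidate threshold not above background threshold")
  list(bg_threshold = bg, candidate_threshold = cand,
       min_hist = min_hist, peak_hist = peak_hist, histogram = hist_df)
}

#' Segment an intensity image into background / tissue / candidate pixels
#'
#' Labels: background where `I < bg_threshold`, candidate where
#' `I > candidate_threshold`, tissue otherwise (values exactly on either
#' threshold are tissue).
#'
#' @param img Intensity image (matrix).
#' @param thresholds Result of [adaptive_thresholds()], or any list with
#'   `bg_threshold < candidate_threshold`.
#' @return A `segmentation_map`: integer matrix of [SEG_BACKGROUND],
#'   [SEG_TISSUE], [SEG_CANDIDATE] with the thresholds attached as
#'   attributes.
#' @export
segment <- function(img, thresholds) {
  bg <- thresholds$bg_threshold; cand <- thresholds$candidate_threshold
  if (!is.finite(bg) || !is.finite(cand) || bg >= cand)
    stop("need bg_threshold < candidate_threshold", call. = FALSE)
  lab <- matrix(SEG_TISSUE, nrow(img), ncol(img))
  lab[img < bg] <- SEG_BACKGROUND
  lab[img > cand] <- SEG_CANDIDATE
  structure(lab, class = "segmentation_map",
            bg_threshold = bg, candidate_threshold = cand)
}

#' Pixel counts per segmentation class
#' @param segmap A `segmentation_map`.
#' @return Named integer vector (`background`, `tissue`, `candidate`).
#' @export
segmentation_counts <- function(segmap) {
  c(background = sum(segmap == SEG_BACKGROUND),
    tissue = sum(segmap == SEG_TISSUE),
    candidate = sum(segmap == SEG_CANDIDATE))
}
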