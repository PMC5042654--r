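#' Relative nanoparticle signal of a field of view
#'
#' The per-pixel nanoparticle signal `s(p)` is the mean intensity over the
#' plasmon band (default 833-988 nm). The relative signal is
#' `sum(s over NP+ pixels) / N_tissue / median(s over NP+ pixels)`, where
#' `N_tissue` is the number of all pixels minus the number of background
#' pixels. The construction is invariant to global intensity scaling
#' (numerator and median both scale) and, with one NP+ pixel, collapses to
#' `1 / N_tissue` by construction.
#'
#' @param cube The (vignette-corrected) [hyper_cube()] the detection was
#'   derived from.
#' @param detection A `detection_map`.
#' @param band A [band_window()]; default [np_band_default()].
#' @return Dimensionless fraction; 0 when no pixel is NP+.
#' @export
relative_np_signal <- function(cube, detection, band = np_band_default()) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(detection, "detection_map"))
  d <- dim(cube$data)
  if (!all(dim(detection$labels) == d[1:2]))
    stop("detection map does not match cube", call. = FALSE)
  n_tissue <- sum(detection$labels != SEG_BACKGROUND)
  if (n_tissue == 0L)
    stop("undefined quantity: no non-background pixels", call. = FALSE)
  np_idx <- which(detection$np_mask)
  if (length(np_idx) == 0L) return(0)
  bidx <- band_indices(cube$grid, band)
  m <- cube$data
  dim(m) <- c(d[1] * d[2], d[3])
  s <- rowMeans(m[np_idx, bidx, drop = FALSE])
  sum(s) / n_tissue / stats::median(s)
}

#' Nanoparticle pixel coverage within a region of interest
#'
#' `#NP+ pixels in the ROI / #non-background pixels in the ROI`. The
#' denominator includes candidate pixels (they are tissue-borne
#' scatterers).
#'
#' @param detection A `detection_map`.
#' @param roi_map Integer matrix of ROI labels (0 = unassigned), same shape.
#' @param roi_label ROI label to quantify.
#' @return Fraction in \[0, 1\].
#' @export
pixel_coverage <- function(detection, roi_map, roi_label) {
  stopifnot(inherits(detection, "detection_map"))
  if (!all(dim(roi_map) == dim(detection$labels)))
    stop("ROI map does not match detection map", call. = FALSE)
  inroi <- roi_map == roi_label
  if (!any(inroi))
    stop("ROI label not present in map", call. = FALSE)
  denom <- sum(inroi & detection$labels != SEG_BACKGROUND)
  if (denom == 0L)
    stop("undefined quantity: ROI has no non-background pixels",
         call. = FALSE)
  sum(inroi & detection$np_mask) / denom
}

#' Aggregate per-field-of-view values into mean, sd and sem
#'
#' @param values Numeric vector of per-FOV measurements.
#' @return List: `n`, `mean`, `sd`, `sem` (sample sd, n-1 denominator;
#'   `sd`/`sem` are `NA` with one value).
#' @export
aggregate_fovs <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)))
    stop("values must be a non-empty finite vector", call. = FALSE)
  n <- length(values)
  if (n == 1L)
    return(list(n = 1L, mean = values, sd = NA_real_, sem = NA_real_))
  s <- stats::sd(values)
  list(n = n, mean = mean(values), sd = s, sem = s / sqrt(n))
}

#' Quantify one field of view, optionally per ROI
#'
#' @param cube Corrected [hyper_cube()].
#' @param detection A `detection_map`.
#' @param band Plasmon [band_window()].
#' @param roi_map Optional ROI label matrix.
#' @param roi_legend Optional named vector mapping label -> ROI name.
#' @return data.frame with one row for the whole image plus one per ROI:
#'   `roi`, `n_np`, `n_tissue`, `coverage`, `relative_signal` (ROI rows
#'   report coverage only; `relative_signal` is a whole-image statistic).
#' @export
quantify_fov <- function(cube, detection, band = np_band_default(),
                         roi_map = NULL, roi_legend = NULL) {
  n_np <- sum(detection$np_mask)
  n_tis <- sum(detection$labels != SEG_BACKGROUND)
  out <- data.frame(
    roi = "whole_image", n_np = n_np, n_tissue = n_tis,
    coverage = if (n_tis > 0L) n_np / n_tis else NA_real_,
    relative_signal = relative_np_signal(cube, detection, band),
    stringsAsFactors = FALSE)
  if (!is.null(roi_map)) {
    labs <- sort(setdiff(unique(as.vector(roi_map)), 0))
    for (l in labs) {
      nm <- if (!is.null(roi_legend) && as.character(l) %in% names(roi_legend))
        roi_legend[[as.character(l)]] else paste0("roi_", l)
      inroi <- roi_map == l
      out <- rbind(out, data.frame(
        roi = nm,
        n_np = sum(inroi & detection$np_mask),
        n_tissue = sum(inroi & detection$labels != SEG_BACKGROUND),
        coverage = pixel_coverage(detection, roi_map, l),
        relative_signal = NA_real_, stringsAsFactors = FALSE))
    }
  }
  out
}
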