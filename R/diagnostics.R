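#' Confusion counts of a detection against a ground-truth mask
#'
#' Scoring is restricted to `eval_mask`; by default only candidate pixels
#' are scored, mirroring a ground-truth protocol in which low-intensity
#' background/tissue pixels are never rated. Set
#' `eval_mask = detection$labels != SEG_BACKGROUND` to score all
#' non-background pixels (whole-image specificity on negative controls).
#'
#' @param detection A `detection_map`.
#' @param truth_np_mask Logical matrix: TRUE where a nanoparticle truly is.
#' @param eval_mask Logical matrix restricting scoring; default candidates.
#' @return List of counts `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_from_truth <- function(detection, truth_np_mask, eval_mask = NULL) {
  stopifnot(inherits(detection, "detection_map"))
  if (!all(dim(truth_np_mask) == dim(detection$labels)))
    stop("truth mask does not match detection map", call. = FALSE)
  if (is.null(eval_mask)) eval_mask <- detection$labels == SEG_CANDIDATE
  if (!any(eval_mask))
    stop("empty evaluation mask", call. = FALSE)
  pred <- detection$np_mask[eval_mask]
  truth <- truth_np_mask[eval_mask]
  list(tp = sum(pred & truth), fp = sum(pred & !truth),
       tn = sum(!pred & !truth), fn = sum(!pred & truth))
}

#' Sensitivity and specificity with log-method confidence intervals
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`; a metric
#' whose denominator is zero is returned as `NA`. 95% intervals (or another
#' `z`) come from [log_method_ci()].
#'
#' @param counts List with `tp`, `fp`, `tn`, `fn` (e.g. from
#'   [confusion_from_truth()]).
#' @param z Normal quantile for the intervals (default 1.96).
#' @return List: `sensitivity`, `specificity`, `sensitivity_ci`,
#'   `specificity_ci`, `counts`.
#' @export
sens_spec <- function(counts, z = 1.96) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0L && tn + fp == 0L)
    stop("no positives or negatives to score", call. = FALSE)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  list(sensitivity = sens, specificity = spec,
       sensitivity_ci = if (!is.na(sens)) log_method_ci(tp, tp + fn, z) else NULL,
       specificity_ci = if (!is.na(spec)) log_method_ci(tn, tn + fp, z) else NULL,
       counts = counts)
}

#' Log-method confidence interval for a proportion
#'
#' For `p = a/n`, the standard error of `log(p)` is
#' `sqrt(1/a - 1/n)`; the interval is `exp(log(p) +/- z * SE)` with the
#' upper bound capped at 1. The log method is undefined at `a = 0`; that
#' case returns `(0, 3/n)` (rule of three) with `zero_numerator = TRUE`.
#'
#' @param numerator Successes `a`, `0 <= a <= n`.
#' @param denominator Trials `n > 0`.
#' @param z Normal quantile (default 1.96 for 95%).
#' @return List: `lo`, `hi`, `estimate`, `zero_numerator`.
#' @export
log_method_ci <- function(numerator, denominator, z = 1.96) {
  a <- numerator; n <- denominator
  if (!is.finite(a) || !is.finite(n) || n <= 0 || a < 0 || a > n)
    stop("need 0 <= numerator <= denominator, denominator > 0",
         call. = FALSE)
  if (a == 0)
    return(list(lo = 0, hi = min(1, 3 / n), estimate = 0,
                zero_numerator = TRUE))
  p <- a / n
  se <- sqrt(1 / a - 1 / n)
  list(lo = p * exp(-z * se), hi = min(1, p * exp(z * se)),
       estimate = p, zero_numerator = FALSE)
}

#' Gaussian point-spread-function standard deviation
#'
#' Paraxial Gaussian approximation of the diffraction-limited spot:
#' `sigma = c * lambda / NA` with `c = 0.21`. At 910 nm and NA 0.75 this
#' gives 0.255 um, i.e. 0.25 um to two decimals.
#'
#' @param wavelength_nm Wavelength (nm), > 0.
#' @param numerical_aperture Objective NA in (0, 1.5].
#' @param c Proportionality constant (default 0.21).
#' @return Standard deviation in nm.
#' @export
psf_sigma <- function(wavelength_nm, numerical_aperture, c = 0.21) {
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stop("wavelength must be > 0", call. = FALSE)
  if (!is.finite(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.5)
    stop("numerical aperture must lie in (0, 1.5]", call. = FALSE)
  c * wavelength_nm / numerical_aperture
}

#' PSF model for the single-particle consistency check
#' @param wavelength_nm Wavelength of the plasmon peak (default 910 nm).
#' @param numerical_aperture Objective NA (default 0.75).
#' @param pixel_pitch_nm Per-axis sampling pitch `c(row, col)` in nm.
#' @return A `psf_model` with derived `sigma_nm`.
#' @export
psf_model <- function(wavelength_nm = 910, numerical_aperture = 0.75,
                      pixel_pitch_nm = c(410, 408)) {
  structure(list(wavelength_nm = wavelength_nm,
                 numerical_aperture = numerical_aperture,
                 sigma_nm = psf_sigma(wavelength_nm, numerical_aperture),
                 pixel_pitch_nm = rep_len(as.numeric(pixel_pitch_nm), 2L)),
            class = "psf_model")
}

#' Single-particle PSF consistency check
#'
#' For an isolated NP+ pixel, extracts horizontal and vertical band-mean
#' intensity profiles through the pixel, max-normalizes them, and compares
#' each with a discrete Gaussian of the theoretical PSF sigma sampled at
#' the pixel pitch. The site is "consistent with a single particle" iff
#' both profile RMSEs are <= 0.1 and the observed peak is within 1 px of
#' the nominal pixel.
#'
#' @param cube A [hyper_cube()].
#' @param detection A `detection_map`; `pixel` must be NP+.
#' @param pixel `c(row, col)` of the candidate single particle.
#' @param psf A [psf_model()].
#' @param band Plasmon [band_window()] for the intensity profiles.
#' @param halfwidth Profile half-width in px (default 4).
#' @param isolation_radius No other NP+ pixel may lie within this Chebyshev
#'   radius (default 5 px); otherwise the check is not applicable.
#' @return List: `applicable`, `isolated`, `peak_offset_px`, `rmse_h`,
#'   `rmse_v`, `consistent`.
#' @export
single_particle_check <- function(cube, detection, pixel,
                                  psf = psf_model(),
                                  band = np_band_default(),
                                  halfwidth = 4L, isolation_radius = 5L) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(detection, "detection_map"))
  r <- pixel[1]; cc <- pixel[2]
  d <- dim(cube$data)
  if (!detection$np_mask[r, cc])
    stop("pixel is not NP+", call. = FALSE)
  rr <- max(1, r - isolation_radius):min(d[1], r + isolation_radius)
  cr <- max(1, cc - isolation_radius):min(d[2], cc + isolation_radius)
  nb <- detection$np_mask[rr, cr, drop = FALSE]
  isolated <- sum(nb) == 1L
  if (!isolated)
    return(list(applicable = FALSE, isolated = FALSE,
                peak_offset_px = NA_real_, rmse_h = NA_real_,
                rmse_v = NA_real_, consistent = NA))
  if (r - halfwidth < 1 || r + halfwidth > d[1] ||
      cc - halfwidth < 1 || cc + halfwidth > d[2])
    return(list(applicable = FALSE, isolated = TRUE,
                peak_offset_px = NA_real_, rmse_h = NA_real_,
                rmse_v = NA_real_, consistent = NA))
  bidx <- band_indices(cube$grid, band)
  bm <- rowMeans(cube$data[, , bidx, drop = FALSE], dims = 2L)
  prof_h <- bm[r, (cc - halfwidth):(cc + halfwidth)]
  prof_v <- bm[(r - halfwidth):(r + halfwidth), cc]
  off <- seq(-halfwidth, halfwidth)
  model_prof <- function(pitch_nm) {
    g <- exp(-0.5 * (off * pitch_nm / psf$sigma_nm)^2)
    g / max(g)
  }
  norm01 <- function(x) {
    x <- x - min(x)
    if (max(x) <= 0) stop("flat intensity profile", call. = FALSE)
    x / max(x)
  }
  ph <- norm01(prof_h); pv <- norm01(prof_v)
  rmse_h <- sqrt(mean((ph - model_prof(psf$pixel_pitch_nm[2]))^2))
  rmse_v <- sqrt(mean((pv - model_prof(psf$pixel_pitch_nm[1]))^2))
  peak_offset <- max(abs(which.max(ph) - (halfwidth + 1)),
                     abs(which.max(pv) - (halfwidth + 1)))
  list(applicable = TRUE, isolated = TRUE,
       peak_offset_px = peak_offset, rmse_h = rmse_h, rmse_v = rmse_v,
       consistent = rmse_h <= 0.1 && rmse_v <= 0.1 && peak_offset <= 1)
}
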