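#' Uniform wavelength grid
#'
#' Constructs the uniform spectral axis shared by all spectra and cubes.
#' The instrument default is 361 samples from 400 to 1000 nm (5/3 nm
#' spacing); any uniform inclusive grid with at least two samples is valid.
#'
#' @param start_nm First wavelength (nm).
#' @param end_nm Last wavelength (nm); must exceed `start_nm`.
#' @param n_samples Number of samples (>= 2).
#' @return A `wavelength_grid` object with fields `start_nm`, `end_nm`,
#'   `n_samples` and the realised `values` vector.
#' @examples
#' g <- wavelength_grid(400, 1000, 361)
#' grid_spacing(g)  # 5/3 nm
#' @export
wavelength_grid <- function(start_nm, end_nm, n_samples) {
  if (!is.numeric(start_nm) || !is.numeric(end_nm) || !is.numeric(n_samples) ||
      length(start_nm) != 1L || length(end_nm) != 1L || length(n_samples) != 1L)
    stop("start_nm, end_nm and n_samples must be scalars", call. = FALSE)
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L)
    stop("a wavelength grid needs at least 2 samples", call. = FALSE)
  if (!is.finite(start_nm) || !is.finite(end_nm) || end_nm <= start_nm)
    stop("grid must be strictly increasing (end_nm > start_nm)", call. = FALSE)
  structure(
    list(start_nm = as.numeric(start_nm), end_nm = as.numeric(end_nm),
         n_samples = n_samples,
         values = seq(start_nm, end_nm, length.out = n_samples)),
    class = "wavelength_grid")
}

#' Default instrument wavelength grid (400-1000 nm, 361 samples)
#' @return A `wavelength_grid`.
#' @export
default_grid <- function() wavelength_grid(400, 1000, 361)

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g..%g nm, %d samples (spacing %.6g nm)\n",
              x$start_nm, x$end_nm, x$n_samples, grid_spacing(x)))
  invisible(x)
}

#' Grid spacing in nm
#' @param grid A `wavelength_grid`.
#' @return Scalar spacing (nm).
#' @export
grid_spacing <- function(grid) {
  stopifnot(inherits(grid, "wavelength_grid"))
  (grid$end_nm - grid$start_nm) / (grid$n_samples - 1L)
}

#' Index of the grid sample closest to a wavelength
#' @param grid A `wavelength_grid`.
#' @param wavelength_nm Target wavelength (nm).
#' @return 1-based index of the nearest sample.
#' @export
nearest_band <- function(grid, wavelength_nm) {
  stopifnot(inherits(grid, "wavelength_grid"), is.finite(wavelength_nm))
  which.min(abs(grid$values - wavelength_nm))
}

grids_equal <- function(a, b, tol = 1e-6) {
  a$n_samples == b$n_samples && max(abs(a$values - b$values)) <= tol
}

#' Truncate a spectrum below a wavelength cutoff
#'
#' Retains exactly the samples with wavelength >= `cutoff_nm`, in order.
#' Short-wavelength channels are noisy on this instrument, so training and
#' classification both operate above a cutoff (default 566 nm elsewhere in
#' the package).
#'
#' @param values Spectrum values, length `grid$n_samples`.
#' @param grid A `wavelength_grid`.
#' @param cutoff_nm Cutoff wavelength; must not exceed the grid end.
#' @return List with `values` (retained samples) and `grid` (sub-grid).
#' @export
truncate_to_cutoff <- function(values, grid, cutoff_nm) {
  stopifnot(inherits(grid, "wavelength_grid"))
  if (length(values) != grid$n_samples)
    stop("spectrum length does not match grid", call. = FALSE)
  if (cutoff_nm > grid$end_nm)
    stop("cutoff beyond grid end: empty result", call. = FALSE)
  keep <- truncate_indices(grid, cutoff_nm)
  sub <- grid$values[keep]
  g <- if (length(sub) >= 2L)
    wavelength_grid(sub[1L], sub[length(sub)], length(sub))
  else
    structure(list(start_nm = sub, end_nm = sub, n_samples = 1L, values = sub),
              class = "wavelength_grid")
  list(values = values[keep], grid = g)
}

truncate_indices <- function(grid, cutoff_nm) {
  keep <- which(grid$values >= cutoff_nm - 1e-9)
  if (length(keep) == 0L)
    stop("cutoff beyond grid end: empty result", call. = FALSE)
  keep
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares local-polynomial smoothing; boundary windows are handled by
#' the polynomial fit itself (no padding), so any polynomial of degree
#' <= `poly_order` is reproduced exactly end to end.
#'
#' @param values Spectrum values.
#' @param window_len Odd window length, > `poly_order`, <= `length(values)`.
#' @param poly_order Polynomial order.
#' @return Smoothed values, same length.
#' @export
smooth_savgol <- function(values, window_len = 11L, poly_order = 3L) {
  window_len <- as.integer(window_len); poly_order <- as.integer(poly_order)
  if (is.na(window_len) || window_len %% 2L == 0L)
    stop("window_len must be odd", call. = FALSE)
  if (window_len <= poly_order)
    stop("window_len must exceed poly_order", call. = FALSE)
  if (window_len > length(values))
    stop("window_len exceeds spectrum length", call. = FALSE)
  if (!all(is.finite(values)))
    stop("spectrum contains non-finite values", call. = FALSE)
  as.numeric(signal::sgolayfilt(values, p = poly_order, n = window_len))
}

#' Normalize a spectrum to unit maximum
#'
#' @param values Spectrum values with a strictly positive, finite maximum.
#' @return `values / max(values)`; output maximum is exactly 1.
#' @export
normalize_max <- function(values) {
  if (!all(is.finite(values)))
    stop("degenerate spectrum: non-finite values", call. = FALSE)
  m <- max(values)
  if (m <= 0)
    stop("degenerate spectrum: maximum is not positive", call. = FALSE)
  values / m
}

#' Closed wavelength band
#' @param lo_nm,hi_nm Band edges in nm, `lo_nm < hi_nm`.
#' @return A `band_window` object.
#' @export
band_window <- function(lo_nm, hi_nm) {
  if (!is.finite(lo_nm) || !is.finite(hi_nm) || lo_nm >= hi_nm)
    stop("band requires lo_nm < hi_nm", call. = FALSE)
  structure(list(lo_nm = lo_nm, hi_nm = hi_nm), class = "band_window")
}

#' Default nanoparticle plasmon band, 833-988 nm
#' @return A `band_window`.
#' @export
np_band_default <- function() band_window(833, 988)

band_indices <- function(grid, band) {
  stopifnot(inherits(grid, "wavelength_grid"), inherits(band, "band_window"))
  if (band$lo_nm < grid$start_nm - 1e-9 || band$hi_nm > grid$end_nm + 1e-9)
    stop("band lies outside the grid range", call. = FALSE)
  idx <- which(grid$values >= band$lo_nm - 1e-9 & grid$values <= band$hi_nm + 1e-9)
  if (length(idx) == 0L)
    stop("band contains no grid samples", call. = FALSE)
  idx
}

#' Mean intensity over a wavelength band
#'
#' Band membership is a closed interval on wavelengths (not indices), so the
#' result is grid-resolution independent.
#'
#' @param values Spectrum values.
#' @param grid A `wavelength_grid` matching `values`.
#' @param band A `band_window` inside the grid.
#' @return Arithmetic mean of the in-band samples.
#' @export
band_mean <- function(values, grid, band) {
  if (length(values) != grid$n_samples)
    stop("spectrum length does not match grid", call. = FALSE)
  mean(values[band_indices(grid, band)])
}

#' Serialize a spectrum (values + grid) to JSON
#' @param values Spectrum values.
#' @param grid Matching `wavelength_grid`.
#' @param path Output file path.
#' @export
write_spectrum_json <- function(values, grid, path) {
  stopifnot(length(values) == grid$n_samples)
  jsonlite::write_json(
    list(grid = list(start = grid$start_nm, end = grid$end_nm,
                     n = grid$n_samples),
         values = values),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrum serialized by [write_spectrum_json()]
#' @param path JSON file path.
#' @return List with `values` and `grid`.
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(values = as.numeric(x$values),
       grid = wavelength_grid(x$grid$start, x$grid$end, x$grid$n))
}
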