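#' Rendering configuration for false-color composites and overlays
#'
#' @param band_centers_nm Red, green, blue channel centres in nm; default
#'   `c(800.0, 700.6, 526.2)`.
#' @param window_len Gaussian integration window length in spectrum samples
#'   (default 80); the window sigma is `(window_len - 1) / 5` samples.
#' @param np_color RGB triplet for nanoparticle-positive pixels (default
#'   orange).
#' @param alt_colors RGB triplets cycled over additional highlighted roles.
#' @return A `render_config` object.
#' @export
render_config <- function(band_centers_nm = c(800.0, 700.6, 526.2),
                          window_len = 80L,
                          np_color = c(1, 0.55, 0),
                          alt_colors = list(c(0, 1, 1), c(0, 1, 0))) {
  window_len <- as.integer(window_len)
  if (is.na(window_len) || window_len < 1L)
    stop("window_len must be >= 1", call. = FALSE)
  if (length(band_centers_nm) != 3L)
    stop("need exactly three channel centres", call. = FALSE)
  structure(list(band_centers_nm = band_centers_nm, window_len = window_len,
                 np_color = np_color, alt_colors = alt_colors),
            class = "render_config")
}

# Gaussian channel weights over the grid, normalized to sum 1
channel_weights <- function(grid, center_nm, window_len) {
  if (center_nm < grid$start_nm || center_nm > grid$end_nm)
    stop("channel centre outside grid", call. = FALSE)
  kc <- nearest_band(grid, center_nm)
  L <- window_len
  pos <- (kc - floor((L - 1) / 2)):(kc - floor((L - 1) / 2) + L - 1L)
  ctr <- pos[1] + (L - 1) / 2
  sigma <- max((L - 1) / 5, 0.5)
  w <- exp(-0.5 * ((pos - ctr) / sigma)^2)
  keep <- pos >= 1L & pos <= grid$n_samples
  out <- numeric(grid$n_samples)
  out[pos[keep]] <- w[keep]
  out / sum(out)
}

#' False-color RGB composite of a hyperspectral cube
#'
#' Each channel is the per-pixel Gaussian-weighted sum of the spectrum
#' around its band centre, then min-max scaled independently to \[0, 1\]
#' ("scaled separately for optimal viewing"); a constant channel maps to 0.
#'
#' @param cube A [hyper_cube()].
#' @param config A [render_config()].
#' @return H x W x 3 array in \[0, 1\].
#' @export
false_color_rgb <- function(cube, config = render_config()) {
  stopifnot(inherits(cube, "hyper_cube"), inherits(config, "render_config"))
  d <- dim(cube$data)
  m <- cube$data
  dim(m) <- c(d[1] * d[2], d[3])
  out <- array(0, c(d[1], d[2], 3L))
  for (ch in 1:3) {
    w <- channel_weights(cube$grid, config$band_centers_nm[ch],
                         config$window_len)
    v <- m %*% w
    rng <- range(v)
    # numerically constant channels map to 0
    out[, , ch] <- if (rng[2] - rng[1] > 1e-12 * max(abs(rng), 1))
      matrix((v - rng[1]) / (rng[2] - rng[1]), d[1], d[2]) else 0
  }
  out
}

#' Detection overlay: grayscale tissue with colored NP+ pixels
#'
#' @param intensity_image Mean-intensity matrix.
#' @param detection A `detection_map`.
#' @param config A [render_config()].
#' @return H x W x 3 array; NP- pixels are the min-max grayscale render,
#'   NP+ pixels are replaced by `config$np_color`.
#' @export
detection_overlay <- function(intensity_image, detection,
                              config = render_config()) {
  stopifnot(inherits(detection, "detection_map"))
  if (!all(dim(intensity_image) == dim(detection$labels)))
    stop("intensity image does not match detection map", call. = FALSE)
  rng <- range(intensity_image)
  g <- if (rng[2] > rng[1])
    (intensity_image - rng[1]) / (rng[2] - rng[1])
  else matrix(0, nrow(intensity_image), ncol(intensity_image))
  out <- array(rep(g, 3L), c(dim(g), 3L))
  for (ch in 1:3) {
    pl <- out[, , ch]
    pl[detection$np_mask] <- config$np_color[ch]
    out[, , ch] <- pl
  }
  out
}

#' Write an RGB or grayscale image array to PNG
#' @param img H x W (grayscale) or H x W x 3 array in \[0, 1\].
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a labeled mask image (single-channel PNG or TIFF)
#'
#' Integer labels are recovered from the 8- or 16-bit sample values.
#' @param path PNG or TIFF path.
#' @return Integer matrix of labels.
#' @export
read_label_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  # readPNG/readTIFF scale integer samples into [0,1]; undo assuming the
  # source bit depth that loses least information
  mx <- max(img)
  scale <- if (mx <= 255 / 65535 + 1e-9) 65535 else 255
  round(img * scale)
}

#' Write an integer label image (8-bit PNG)
#' @param labels Integer matrix with values in 0..255.
#' @param path Output PNG path.
#' @export
write_label_image <- function(labels, path) {
  if (max(labels) > 255 || min(labels) < 0)
    stop("labels must fit 8 bits", call. = FALSE)
  png::writePNG(labels / 255, path)
  invisible(path)
}
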