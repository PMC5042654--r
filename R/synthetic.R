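#' Lorentzian line-shape spectrum
#'
#' Single-resonance surrogate for a plasmonic scattering peak:
#' `v(lambda) = baseline + A * gamma^2 / ((lambda - center)^2 + gamma^2)`.
#' The full width at half maximum is `2 * gamma`.
#'
#' @param center_nm Resonance centre (nm).
#' @param gamma_nm Half-width at half maximum (nm), > 0.
#' @param amplitude Peak height above baseline, > 0.
#' @param baseline Additive offset (default 0).
#' @param grid A [wavelength_grid()].
#' @return Spectrum values on the grid.
#' @export
lorentzian_spectrum <- function(center_nm, gamma_nm, amplitude = 1,
                                baseline = 0, grid = default_grid()) {
  if (!is.finite(gamma_nm) || gamma_nm <= 0)
    stop("gamma_nm must be > 0", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  baseline + amplitude * gamma_nm^2 /
    ((grid$values - center_nm)^2 + gamma_nm^2)
}

#' Broad Gaussian spectrum (stain scattering surrogate)
#' @param center_nm Centre (nm).
#' @param sigma_nm Standard deviation (nm), > 0.
#' @param amplitude Peak height.
#' @param baseline Additive offset.
#' @param grid A [wavelength_grid()].
#' @return Spectrum values on the grid.
#' @export
gaussian_spectrum <- function(center_nm, sigma_nm, amplitude = 1,
                              baseline = 0, grid = default_grid()) {
  if (!is.finite(sigma_nm) || sigma_nm <= 0)
    stop("sigma_nm must be > 0", call. = FALSE)
  baseline + amplitude * exp(-0.5 * ((grid$values - center_nm) / sigma_nm)^2)
}

#' Hybridized (aggregate) spectrum: blue-shifted split resonance
#'
#' Plasmon hybridization in close-packed particles blue-shifts the
#' resonance and splits it; modelled as the sum of two Lorentzians at
#' `center - blue_shift +/- split_sep / 2`. Two local maxima appear when
#' `split_sep > 2 * gamma`.
#'
#' @param center_nm Single-particle resonance centre (nm).
#' @param gamma_nm Half-width of each component (nm).
#' @param blue_shift_nm Blue shift of the doublet midpoint (nm, >= 0).
#' @param split_sep_nm Separation of the two components (nm, > 0).
#' @param amplitude Per-component peak height.
#' @param grid A [wavelength_grid()].
#' @return Spectrum values on the grid.
#' @export
hybridized_spectrum <- function(center_nm, gamma_nm, blue_shift_nm = 60,
                                split_sep_nm = 120, amplitude = 1,
                                grid = default_grid()) {
  if (!is.finite(split_sep_nm) || split_sep_nm <= 0)
    stop("split_sep_nm must be > 0", call. = FALSE)
  mid <- center_nm - blue_shift_nm
  lorentzian_spectrum(mid - split_sep_nm / 2, gamma_nm, amplitude,
                      grid = grid) +
    lorentzian_spectrum(mid + split_sep_nm / 2, gamma_nm, amplitude,
                        grid = grid)
}

#' Phantom generator configuration
#'
#' Defines one synthetic dark-field scene: stained tissue blobs, nanorod-like
#' point scatterers convolved with the instrument PSF, hybridized
#' aggregates, chromatic-aberration edge artifacts on the tissue boundary,
#' cosine-fourth vignetting, and sensor noise. A fixed `seed` makes the
#' scene fully deterministic.
#'
#' @param height,width Image size in pixels.
#' @param grid A [wavelength_grid()] (default instrument grid).
#' @param seed RNG seed.
#' @param n_blobs Number of elliptical tissue blobs.
#' @param blob_r_frac Blob semi-axis range as a fraction of the smaller
#'   image dimension.
#' @param stained Stained tissue (hematoxylin/eosin surrogates) or a single
#'   neutral broadband scatter model.
#' @param tissue_amp Median tissue spectral peak amplitude (intensity units).
#' @param tissue_amp_sdlog Log-sd of the per-pixel tissue amplitude.
#' @param np_density Single-particle count as a fraction of tissue pixels.
#' @param np_count Absolute particle count; overrides `np_density` (used by
#'   the pure-particle mixture preset where no tissue is present).
#' @param np_center_nm In-water resonance centre of the particle (nm).
#' @param np_gamma_nm Resonance half-width (nm).
#' @param np_amplitude Particle spectral peak amplitude before PSF spread.
#' @param np_center_jitter_nm Per-particle centre jitter sd (nm).
#' @param medium_shift_nm Red shift from the mounting medium's refractive
#'   index (default +80 nm); the in-situ resonance is
#'   `np_center_nm + medium_shift_nm`.
#' @param np2_density,np2_count,np2_center_nm,np2_gamma_nm,np2_amplitude
#'   Optional second particle species (broad nanoshell-like by default).
#' @param aggregate_fraction Fraction of species-1 particles that are
#'   hybridized aggregates.
#' @param agg_amplitude_mult Aggregate amplitude multiplier (aggregates are
#'   brighter).
#' @param agg_blue_shift_nm,agg_split_nm Hybridization blue shift and peak
#'   separation (nm).
#' @param edge_artifact_rate Fraction of tissue-boundary pixels carrying a
#'   chromatic-aberration artifact spectrum.
#' @param edge_center_nm,edge_gamma_nm,edge_amplitude Artifact resonance
#'   parameters: near the particle resonance but much broader.
#' @param numerical_aperture,pitch_nm Optics for the PSF (sigma from
#'   [psf_sigma()] at the in-situ resonance wavelength).
#' @param d_mm Vignetting falloff distance (mm).
#' @param bg_amp Background (noise-floor) flat spectral amplitude.
#' @param noise_sigma_rel Gaussian noise sd relative to each pixel's
#'   spectral peak.
#' @param poisson Add Poisson (shot) noise as well.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(height = 128L, width = 128L, grid = default_grid(),
                           seed = 1L,
                           n_blobs = 4L, blob_r_frac = c(0.12, 0.28),
                           stained = TRUE,
                           tissue_amp = 200, tissue_amp_sdlog = 0.25,
                           np_density = 0.002, np_count = NULL,
                           np_center_nm = 820, np_gamma_nm = 30,
                           np_amplitude = 10000, np_center_jitter_nm = 5,
                           medium_shift_nm = 80,
                           np2_density = 0, np2_count = NULL,
                           np2_center_nm = 720, np2_gamma_nm = 90,
                           np2_amplitude = 10000,
                           aggregate_fraction = 0.1,
                           agg_amplitude_mult = 2,
                           agg_blue_shift_nm = 120, agg_split_nm = 160,
                           edge_artifact_rate = 0.05,
                           edge_center_nm = 915, edge_gamma_nm = 90,
                           edge_amplitude = 800,
                           numerical_aperture = 0.75,
                           pitch_nm = c(410, 408),
                           d_mm = 2,
                           bg_amp = 2,
                           noise_sigma_rel = 0.05, poisson = FALSE) {
  cfg <- as.list(environment())
  for (f in c("np_density", "np2_density", "aggregate_fraction",
              "edge_artifact_rate"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(f, " must lie in [0, 1]", call. = FALSE)
  if (height < 8L || width < 8L)
    stop("phantom must be at least 8 x 8 pixels", call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Phantom presets for the studied particle types
#'
#' * `"lgnr"`: stained tissue with narrow NIR nanorod-like particles
#'   (900 nm in situ) plus aggregates and edge artifacts.
#' * `"nanoshell"`: as `"lgnr"` with a broad ~800 nm resonance.
#' * `"gns"`: unstained tissue with a visible ~550 nm nanosphere-like
#'   resonance.
#' * `"mixture"`: pure-particle slide, no tissue: narrow ~900 nm and broad
#'   ~800 nm species mixed on a dark background.
#'
#' @param preset One of `"lgnr"`, `"nanoshell"`, `"gns"`, `"mixture"`.
#' @param seed RNG seed.
#' @param ... Overrides forwarded to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_preset <- function(preset = c("lgnr", "nanoshell", "gns", "mixture"),
                           seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    lgnr = list(),
    nanoshell = list(np_center_nm = 720, np_gamma_nm = 90),
    gns = list(np_center_nm = 470, np_gamma_nm = 40, stained = FALSE,
               aggregate_fraction = 0, edge_center_nm = 620,
               edge_gamma_nm = 80),
    mixture = list(n_blobs = 0L, np_count = 150L, np2_count = 150L,
                   aggregate_fraction = 0, edge_artifact_rate = 0))
  over <- list(...)
  args[names(over)] <- over
  args$seed <- seed
  do.call(phantom_config, args)
}

# pixel-integrated 2-d Gaussian patch weights for a sub-pixel source
psf_patch <- function(sub_r, sub_c, sigma_px, half = 3L) {
  off <- seq(-half, half)
  ax <- function(s, sub, i) {
    stats::pnorm((i + 0.5 - sub) / s) - stats::pnorm((i - 0.5 - sub) / s)
  }
  wr <- ax(sigma_px[1], sub_r, off)
  wc <- ax(sigma_px[2], sub_c, off)
  outer(wr, wc)
}

# bilinear upsampling of a coarse field to h x w
upsample_field <- function(coarse, h, w) {
  ch <- nrow(coarse); cw <- ncol(coarse)
  ri <- seq(1, ch, length.out = h)
  ci <- seq(1, cw, length.out = w)
  r0 <- pmin(floor(ri), ch - 1L); c0 <- pmin(floor(ci), cw - 1L)
  fr <- ri - r0; fc <- ci - c0
  a <- coarse[r0, c0, drop = FALSE]; b <- coarse[r0 + 1L, c0, drop = FALSE]
  cc <- coarse[r0, c0 + 1L, drop = FALSE]; d <- coarse[r0 + 1L, c0 + 1L, drop = FALSE]
  a * outer(1 - fr, 1 - fc) + b * outer(fr, 1 - fc) +
    cc * outer(1 - fr, fc) + d * outer(fr, fc)
}

#' Generate a synthetic phantom scene with ground truth
#'
#' Composes (in order): dark background floor; tissue blobs with a smoothly
#' varying hematoxylin/eosin stain mixture; single particles as sub-pixel
#' point sources convolved with the Gaussian PSF; brighter hybridized
#' aggregates; chromatic-aberration artifacts on a random subset of
#' tissue-boundary pixels; cosine-fourth vignetting; Gaussian (optionally
#' Poisson) noise. Deterministic for a fixed `config$seed`.
#'
#' @param config A [phantom_config()] or [phantom_preset()].
#' @return List: `cube` (a [hyper_cube()]), `truth` (masks `background`,
#'   `tissue`, `np_single`, `np_aggregate`, `np_halo`, `edge_artifact`,
#'   species matrix `np_species`, and per-particle `positions`), and the
#'   `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  cf <- config
  with_seed(cf$seed, {
    h <- cf$height; w <- cf$width; g <- cf$grid; B <- g$n_samples
    npix <- h * w

    # --- tissue geometry: union of random ellipses ---
    tissue <- matrix(FALSE, h, w)
    if (cf$n_blobs > 0L) {
      rows <- matrix(seq_len(h), h, w)
      cols <- matrix(seq_len(w), h, w, byrow = TRUE)
      rmin <- min(h, w)
      for (i in seq_len(cf$n_blobs)) {
        cr <- stats::runif(1, 0.2 * h, 0.8 * h)
        cc <- stats::runif(1, 0.2 * w, 0.8 * w)
        ar <- stats::runif(1, cf$blob_r_frac[1], cf$blob_r_frac[2]) * rmin
        br <- stats::runif(1, cf$blob_r_frac[1], cf$blob_r_frac[2]) * rmin
        th <- stats::runif(1, 0, pi)
        x <- (rows - cr) * cos(th) + (cols - cc) * sin(th)
        y <- -(rows - cr) * sin(th) + (cols - cc) * cos(th)
        tissue <- tissue | ((x / ar)^2 + (y / br)^2 <= 1)
      }
    }

    # --- spectral templates ---
    np_center <- cf$np_center_nm + cf$medium_shift_nm
    np_spec <- lorentzian_spectrum(np_center, cf$np_gamma_nm, 1, grid = g)
    np2_center <- cf$np2_center_nm + cf$medium_shift_nm
    np2_spec <- lorentzian_spectrum(np2_center, cf$np2_gamma_nm, 1, grid = g)
    edge_spec <- lorentzian_spectrum(cf$edge_center_nm, cf$edge_gamma_nm, 1,
                                     grid = g)
    if (cf$stained) {
      s_hema <- gaussian_spectrum(540, 80, 1, grid = g)
      s_eosin <- gaussian_spectrum(650, 90, 1, grid = g)
    } else {
      s_hema <- s_eosin <- gaussian_spectrum(600, 150, 1, grid = g)
    }

    # spectra matrix, pixels (column-major) x bands
    M <- matrix(cf$bg_amp, npix, B)

    # --- tissue spectra: smooth stain-mixture field ---
    t_idx <- which(tissue)
    if (length(t_idx) > 0L) {
      mixf <- upsample_field(matrix(stats::runif(64), 8, 8), h, w)
      amp <- cf$tissue_amp *
        stats::rlnorm(length(t_idx), 0, cf$tissue_amp_sdlog)
      wmix <- mixf[t_idx]
      M[t_idx, ] <- M[t_idx, ] +
        (amp * wmix) %o% s_hema + (amp * (1 - wmix)) %o% s_eosin
    }

    # --- particle placement ---
    boundary <- tissue &
      !(shift_mat(tissue, 1, 0) & shift_mat(tissue, -1, 0) &
        shift_mat(tissue, 0, 1) & shift_mat(tissue, 0, -1))
    # keep particles off the image rim so PSF patches stay in frame
    rim <- matrix(FALSE, h, w)
    rim[1:4, ] <- TRUE; rim[(h - 3):h, ] <- TRUE
    rim[, 1:4] <- TRUE; rim[, (w - 3):w] <- TRUE
    placeable <- if (length(t_idx) > 0L) which(tissue & !boundary & !rim)
                 else which(!rim)
    n1 <- if (!is.null(cf$np_count)) cf$np_count
          else round(cf$np_density * length(t_idx))
    n2 <- if (!is.null(cf$np2_count)) cf$np2_count
          else round(cf$np2_density * length(t_idx))
    n1 <- min(n1, length(placeable)); n2 <- min(n2, max(0L, length(placeable) - n1))
    n_agg <- round(cf$aggregate_fraction * n1)
    picks <- if (n1 + n2 > 0L) sample(placeable, n1 + n2) else integer(0)

    sigma_px <- psf_sigma(np_center, cf$numerical_aperture) / cf$pitch_nm
    sigma2_px <- psf_sigma(np2_center, cf$numerical_aperture) / cf$pitch_nm

    np_single <- np_aggregate <- edge_mask <- matrix(FALSE, h, w)
    np_species <- matrix(0L, h, w)
    halo_w <- matrix(0, h, w)
    pos <- list()
    half <- 3L
    add_particle <- function(M, lin, species, aggregate) {
      r <- ((lin - 1L) %% h) + 1L; c <- ((lin - 1L) %/% h) + 1L
      sub_r <- stats::runif(1, -0.5, 0.5); sub_c <- stats::runif(1, -0.5, 0.5)
      jit <- stats::rnorm(1, 0, cf$np_center_jitter_nm)
      if (species == 1L) {
        spec <- if (aggregate)
          hybridized_spectrum(np_center + jit, cf$np_gamma_nm,
                              cf$agg_blue_shift_nm, cf$agg_split_nm,
                              1, grid = g)
        else lorentzian_spectrum(np_center + jit, cf$np_gamma_nm, 1, grid = g)
        amp <- cf$np_amplitude * (if (aggregate) cf$agg_amplitude_mult else 1)
        sp <- sigma_px
      } else {
        spec <- lorentzian_spectrum(np2_center + jit, cf$np2_gamma_nm, 1,
                                    grid = g)
        amp <- cf$np2_amplitude
        sp <- sigma2_px
      }
      wts <- psf_patch(sub_r, sub_c, sp, half)
      pr <- (r - half):(r + half); pc <- (c - half):(c + half)
      lin_patch <- rep(pr, times = 2 * half + 1) +
        (rep(pc, each = 2 * half + 1) - 1L) * h
      M[lin_patch, ] <- M[lin_patch, ] + (amp * as.vector(wts)) %o% spec
      halo_w[lin_patch] <<- halo_w[lin_patch] + as.vector(wts)
      pos[[length(pos) + 1L]] <<- data.frame(
        row = r, col = c, sub_row = r + sub_r, sub_col = c + sub_c,
        species = species, aggregate = aggregate)
      M
    }
    if (n1 + n2 > 0L) {
      for (j in seq_len(n1)) {
        lin <- picks[j]
        agg <- j <= n_agg
        M <- add_particle(M, lin, 1L, agg)
        if (agg) np_aggregate[lin] <- TRUE else np_single[lin] <- TRUE
        np_species[lin] <- 1L
      }
      for (j in seq_len(n2)) {
        lin <- picks[n1 + j]
        M <- add_particle(M, lin, 2L, FALSE)
        np_single[lin] <- TRUE
        np_species[lin] <- 2L
      }
    }

    # --- edge artifacts on the tissue boundary ---
    b_idx <- which(boundary & !rim)
    if (length(b_idx) > 0L && cf$edge_artifact_rate > 0) {
      ne <- round(cf$edge_artifact_rate * length(b_idx))
      if (ne > 0L) {
        sel <- sample(b_idx, ne)
        eamp <- cf$edge_amplitude * stats::rlnorm(ne, 0, 0.2)
        M[sel, ] <- M[sel, ] + eamp %o% edge_spec
        edge_mask[sel] <- TRUE
      }
    }

    # --- vignetting, then noise last ---
    vf <- vignette_factors(vignette_model(cf$d_mm, cf$pitch_nm), c(h, w))
    M <- M * as.vector(vf)
    if (cf$noise_sigma_rel > 0) {
      sdv <- cf$noise_sigma_rel * apply(M, 1L, max)
      M <- M + matrix(stats::rnorm(npix * B), npix, B) * sdv
    }
    if (cf$poisson) M <- matrix(stats::rpois(npix * B, pmax(M, 0)), npix, B)
    M[M < 0] <- 0

    cube_arr <- M
    dim(cube_arr) <- c(h, w, B)
    positions <- if (length(pos)) do.call(rbind, pos) else
      data.frame(row = integer(0), col = integer(0), sub_row = numeric(0),
                 sub_col = numeric(0), species = integer(0),
                 aggregate = logical(0))
    truth <- list(
      background = !tissue, tissue = tissue,
      np_single = np_single, np_aggregate = np_aggregate,
      np_halo = (halo_w > 0.05) & !np_single & !np_aggregate,
      edge_artifact = edge_mask, np_species = np_species,
      positions = positions,
      np_template = np_spec, np2_template = np2_spec,
      edge_template = edge_spec, np_center_nm = np_center,
      np2_center_nm = np2_center)
    list(cube = hyper_cube(cube_arr, g), truth = truth, config = cf)
  })
}

# toroidal-free shift with FALSE fill (for boundary detection)
shift_mat <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(FALSE, h, w)
  rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}
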