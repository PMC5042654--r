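# shared fixtures: small phantoms and hand-built cubes, all generated in code

# tiny deterministic cube with arbitrary positive values
tiny_cube <- function(h = 2, w = 2, b = 3, seed = 7) {
  g <- wavelength_grid(400, 400 + 10 * (b - 1), b)
  set.seed(seed)
  hyper_cube(array(round(runif(h * w * b, 1, 100)), c(h, w, b)), g)
}

# small stained-tissue phantom, vignette-corrected, with segmentation
small_scene <- function(seed = 1, size = 96, ...) {
  ph <- generate_phantom(phantom_preset("lgnr", seed = seed,
                                        height = size, width = size, ...))
  ph$cube <- vignette_correct(ph$cube)
  img <- mean_intensity(ph$cube)
  th <- adaptive_thresholds(img)
  ph$segmap <- segment(img, th)
  ph$intensity <- img
  ph
}

# independent per-pixel preprocessing oracle: truncate, SG-smooth, normalize
preprocess_oracle <- function(spec, grid, cutoff = 566, win = 11, ord = 3) {
  keep <- which(grid$values >= cutoff - 1e-9)
  v <- signal::sgolayfilt(spec[keep], p = ord, n = win)
  v / max(v)
}
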