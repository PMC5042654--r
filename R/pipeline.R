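config_error <- function(msg) {
  stop(structure(class = c("hsmad_config_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}
data_error <- function(msg) {
  stop(structure(class = c("hsmad_data_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Default end-to-end pipeline configuration
#'
#' One nested document holding every stage's tunables, with the instrument
#' defaults: 566 nm cutoff, Savitzky-Golay 11/3, 510 histogram bins
#' resampled every 5 intensity units, cos^4 vignetting with d = 2 mm and
#' 410 x 408 nm pitch, k = 4 clusters, plasmon band 833-988 nm, render
#' channels 800.0/700.6/526.2 nm with an 80-sample window.
#'
#' @return Nested list (`schema_version`, `seed`, `preprocess`,
#'   `thresholds`, `vignette`, `train`, `quantify`, `render`, `inputs`).
#' @export
default_pipeline_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    preprocess = list(cutoff_nm = 566, sg_window = 11L, sg_order = 3L),
    thresholds = list(n_bins = 510L, resample_step = 5, alpha = 1.05,
                      beta = 1.5),
    vignette = list(d_mm = 2, pitch_nm = c(410, 408)),
    train = list(k = 4L, n_restarts = 10L,
                 np_band = c(833, 988)),
    quantify = list(band = c(833, 988)),
    render = list(band_centers_nm = c(800.0, 700.6, 526.2),
                  window_len = 80L),
    inputs = list())
}

# deep-merge user values over defaults
merge_config <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(base[[nm]]) && is.list(over[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], over[[nm]])
    else base[[nm]] <- over[[nm]]
  }
  base
}

#' Build and validate a pipeline configuration
#'
#' @param ... Overrides of [default_pipeline_config()] fields (nested lists
#'   are deep-merged).
#' @return Validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- merge_config(default_pipeline_config(), list(...))
  validate_pipeline_config(cfg)
  cfg
}

#' @rdname pipeline_config
#' @param config A config list to validate.
#' @export
validate_pipeline_config <- function(config) {
  inp <- config$inputs
  has_train <- !is.null(inp$train_paths) || !is.null(inp$simulate)
  if (is.null(inp$library_path) && !has_train)
    config_error(paste("config field 'inputs' must provide either",
                       "'library_path' or training data",
                       "('train_paths' or 'simulate')"))
  if (is.null(inp$simulate) && is.null(inp$test_paths))
    config_error("config field 'inputs.test_paths' is required without 'inputs.simulate'")
  th <- config$thresholds
  if (th$alpha < 1 || th$beta < 1)
    config_error("config fields 'thresholds.alpha'/'thresholds.beta' must be >= 1")
  invisible(config)
}

log_line <- function(con, stage, ...) {
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage = stage), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
}

# segment one corrected cube; returns segmap + thresholds
segment_cube <- function(cube, cfg) {
  img <- mean_intensity(cube)
  th <- adaptive_thresholds(img, threshold_params(
    cfg$thresholds$n_bins, cfg$thresholds$resample_step,
    cfg$thresholds$alpha, cfg$thresholds$beta))
  list(segmap = segment(img, th), thresholds = th, intensity = img)
}

#' Run the full detection pipeline
#'
#' Chains every stage on a single configuration: load (or simulate) cubes,
#' vignette-correct, segment adaptively, train the spectral library (or
#' load one), optionally learn the chromatic-aberration cluster from
#' negative controls, classify every test image, quantify, and render. All
#' thresholds, seeds and artifacts are written into `out_dir`; outputs
#' depend only on (config, inputs).
#'
#' With `inputs$simulate = list(preset, train_seeds, control_seeds,
#' test_seeds, ...)` the pipeline generates its own phantoms; otherwise
#' `inputs$train_paths` / `control_paths` / `test_paths` name ENVI headers.
#'
#' @param config List from [pipeline_config()].
#' @param out_dir Run directory (created).
#' @return Invisibly, a list with the library, per-image detections and the
#'   quantification data.frame.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "log.jsonl"), "w")
  on.exit(close(logf))
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  ppc <- preprocess_config(config$preprocess$cutoff_nm,
                           config$preprocess$sg_window,
                           config$preprocess$sg_order)
  vmod <- vignette_model(config$vignette$d_mm, config$vignette$pitch_nm)
  qband <- band_window(config$quantify$band[1], config$quantify$band[2])
  np_band <- band_window(config$train$np_band[1], config$train$np_band[2])

  sim <- config$inputs$simulate
  load_group <- function(paths, seeds, role) {
    if (!is.null(sim)) {
      lapply(seeds, function(s) {
        ov <- sim; ov$preset <- NULL; ov$train_seeds <- NULL
        ov$control_seeds <- NULL; ov$test_seeds <- NULL
        if (identical(role, "control")) ov$np_density <- 0
        cfg <- do.call(phantom_preset,
                       c(list(preset = sim$preset, seed = s), ov))
        generate_phantom(cfg)$cube
      })
    } else {
      lapply(paths, function(p) {
        tryCatch(read_envi(p), error = function(e) data_error(conditionMessage(e)))
      })
    }
  }
  train_cubes <- load_group(config$inputs$train_paths, sim$train_seeds, "train")
  control_cubes <- load_group(config$inputs$control_paths, sim$control_seeds,
                              "control")
  test_cubes <- load_group(config$inputs$test_paths, sim$test_seeds, "test")
  log_line(logf, "load", n_train = length(train_cubes),
           n_control = length(control_cubes), n_test = length(test_cubes))

  prep <- function(cube) vignette_correct(cube, vmod)
  train_cubes <- lapply(train_cubes, prep)
  control_cubes <- lapply(control_cubes, prep)
  test_cubes <- lapply(test_cubes, prep)

  # --- library ---
  if (!is.null(config$inputs$library_path)) {
    lib <- read_library(config$inputs$library_path)
    log_line(logf, "library", source = config$inputs$library_path)
  } else {
    train_segs <- lapply(train_cubes, segment_cube, cfg = config)
    for (i in seq_along(train_segs))
      log_line(logf, "segment_train", image = i,
               bg_threshold = train_segs[[i]]$thresholds$bg_threshold,
               candidate_threshold = train_segs[[i]]$thresholds$candidate_threshold)
    tp <- collect_training_pixels(train_cubes,
                                  lapply(train_segs, `[[`, "segmap"), ppc)
    km <- train_kmeans(tp$pixels, config$train$k, seed = config$seed,
                       n_restarts = config$train$n_restarts)
    lib <- assemble_library(km$centroids, tp$grid, ppc$cutoff_nm,
                            np_band = np_band, k = config$train$k,
                            seed = config$seed)
    log_line(logf, "train", k = config$train$k, seed = config$seed,
             n_pixels = nrow(tp$pixels), objective = km$objective,
             np_index = lib$np_index)
    if (length(control_cubes) > 0L) {
      ctl_segs <- lapply(control_cubes, segment_cube, cfg = config)
      ab <- build_aberration_cluster(control_cubes,
                                     lapply(ctl_segs, `[[`, "segmap"),
                                     lib, ppc)
      if (!is.null(ab)) {
        lib <- assemble_library(km$centroids, tp$grid, ppc$cutoff_nm,
                                np_band = np_band,
                                manual = list(list(values = ab,
                                                   role = "aberration")),
                                k = config$train$k, seed = config$seed)
        log_line(logf, "aberration_cluster", added = TRUE)
      } else log_line(logf, "aberration_cluster", added = FALSE)
    }
    write_library(lib, file.path(out_dir, "library.json"))
  }

  # --- classification + quantification + rendering ---
  rcfg <- render_config(config$render$band_centers_nm, config$render$window_len)
  quant <- NULL; detections <- list()
  for (i in seq_along(test_cubes)) {
    sc <- segment_cube(test_cubes[[i]], config)
    det <- classify_nearest_centroid(test_cubes[[i]], sc$segmap, lib, ppc)
    detections[[i]] <- det
    jsonlite::write_json(
      list(bg_threshold = sc$thresholds$bg_threshold,
           candidate_threshold = sc$thresholds$candidate_threshold),
      file.path(out_dir, sprintf("test_%02d_thresholds.json", i)),
      auto_unbox = TRUE, digits = NA)
    write_image_png(detection_overlay(sc$intensity, det, rcfg),
                    file.path(out_dir, sprintf("test_%02d_detection.png", i)))
    write_image_png(false_color_rgb(test_cubes[[i]], rcfg),
                    file.path(out_dir, sprintf("test_%02d_falsecolor.png", i)))
    utils::write.csv(detection_counts(det),
                     file.path(out_dir, sprintf("test_%02d_counts.csv", i)),
                     row.names = FALSE)
    q <- quantify_fov(test_cubes[[i]], det, qband)
    q <- cbind(fov = i, q)
    quant <- rbind(quant, q)
    log_line(logf, "classify", image = i, n_np = sum(det$np_mask))
  }
  utils::write.csv(quant, file.path(out_dir, "quantification.csv"),
                   row.names = FALSE)
  if (nrow(quant[quant$roi == "whole_image", ]) >= 2L) {
    ag <- aggregate_fovs(quant$relative_signal[quant$roi == "whole_image"])
    jsonlite::write_json(ag, file.path(out_dir, "aggregate.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  log_line(logf, "done")
  invisible(list(library = lib, detections = detections, quant = quant))
}
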