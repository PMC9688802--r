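# Pipeline stages over files: simulate -> extract -> calibrate / train /
# predict / stability.  Every stage is a plain function over a config
# list so runs are scriptable and reproducible from one seed.

#' Default pipeline configuration
#'
#' A nested list of all tunable parameters, overridable by name.  The
#' default simulated study covers the physiological 0.5-20 mM range
#' (9 levels) plus the molar excess range 0.1-0.5 M (5 levels), three
#' replicates each.
#'
#' @param ... named overrides, e.g. `seed = 7` or
#'   `scene = list(noise_sd = 2)` (partial lists are merged).
#' @return Configuration list.
#' @export
glucopad_config <- function(...) {
  cfg <- list(
    seed = 1L,
    model = list(a = 36.958, b = 61.367, clamp_lo = 0, clamp_hi = 255),
    scene = list(image_size = c(192L, 192L), spot_radius = 60,
                 paper_rgb = c(0.96, 0.95, 0.92),
                 stain_rgb = c(0.35, 0.24, 0.08),
                 illum_gradient = 0, noise_sd = 4, radial_amplitude = 0.06),
    simulate = list(concentrations_mM = c(0.5, 1, 2, 5, 8, 11, 14, 17, 20,
                                          100, 200, 300, 400, 500),
                    replicates = 3L, write_masks = FALSE),
    preprocess = list(target_size = c(256L, 256L), denoise_kernel = 3L),
    segment = list(shrink_factor = 0.8, min_area = 50L, opening_size = 5L),
    features = list(Ng = 8L, offset = c(0L, 1L), symmetric = TRUE),
    calibration = list(valid_range = c(0.5, 14), fit_range = c(0.5, 20),
                       lod_k = 3.3),
    train = list(kernel = "rbf", cv_folds = 2L, train_fraction = 0.7),
    stability = list(conc_mM = 8, days = c(0L, 2L, 4L, 7L, 10L, 14L),
                     decay_fraction_at_end = 0.62, replicates = 3L,
                     condition = "trehalose/4C"))
  overrides <- list(...)
  for (nm in names(overrides)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      utils::modifyList(cfg[[nm]], overrides[[nm]])
    } else overrides[[nm]]
  }
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config configuration list.
#' @return The configuration list (`read_config`), or `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  do.call(glucopad_config, cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_scene <- function(config) {
  do.call(scene_params, c(config$scene, list(seed = config$seed)))
}

config_model <- function(config) do.call(response_model, config$model)

#' Stage 1: simulate the assay image set
#'
#' @param config a [glucopad_config()].
#' @param out_dir directory receiving the PNGs and `manifest.csv`.
#' @return The manifest data.frame, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- simulate_dataset(config_model(config), config_scene(config),
                          concentrations = config$simulate$concentrations_mM,
                          replicates = config$simulate$replicates,
                          seed = config$seed, out_dir = out_dir,
                          write_masks = isTRUE(config$simulate$write_masks))
  invisible(sim$manifest)
}

#' Stage 2: extract feature vectors for every manifest image
#'
#' Reads each image, preprocesses and segments it, and computes the
#' 51-entry feature vector plus background-response statistics (used as
#' the blank estimate by calibration).
#'
#' @param manifest manifest data.frame or path to a manifest CSV; paths
#'   are resolved relative to the CSV location.
#' @param config a [glucopad_config()].
#' @param out_csv optional output CSV path.
#' @return data.frame: manifest columns, 51 features,
#'   `bg_response_mean`, `bg_response_sd`.
#' @export
run_extract <- function(manifest, config = glucopad_config(), out_csv = NULL) {
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    manifest$image_path <- ifelse(file.exists(manifest$image_path),
                                  manifest$image_path,
                                  file.path(base, manifest$image_path))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$image_path[i]
    if (!file.exists(path)) {
      stop(sprintf("manifest references a missing image: %s", path), call. = FALSE)
    }
    img <- read_spot_image(path)
    img <- preprocess(img, target_size = config$preprocess$target_size,
                      denoise_kernel = config$preprocess$denoise_kernel)
    roi <- segment_spot(img, shrink_factor = config$segment$shrink_factor,
                        min_area = config$segment$min_area,
                        opening_size = config$segment$opening_size)
    fv <- extract_features(img, roi, Ng = config$features$Ng,
                           offset = config$features$offset,
                           symmetric = config$features$symmetric)
    # background (blank) statistics: pixels beyond 1.2 x fitted radius
    h <- dim(img)[1]; w <- dim(img)[2]
    rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
    bgm <- (rr - roi$center[1])^2 + (cc - roi$center[2])^2 > (1.2 * roi$radius)^2
    bg_resp <- rgb_to_gray(extract_roi_pixels(img, bgm))[, "response"]
    cbind(manifest[i, , drop = FALSE],
          as.data.frame(t(fv)),
          bg_response_mean = mean(bg_resp), bg_response_sd = stats::sd(bg_resp))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Stage 3: fit the calibration curve from a feature table
#'
#' The per-image response is `255 - gray_intensity` (inverted gray).
#' Only images within `calibration$fit_range` contribute to the fit; the
#' blank statistics are the averaged background-response mean and the
#' per-pixel background standard deviation.
#'
#' @param features feature table from [run_extract()] (data.frame or CSV
#'   path).
#' @param config a [glucopad_config()].
#' @param out_json optional path for the serialized fit.
#' @return A [fit_log_calibration()] object with `lod` filled in when a
#'   blank estimate is available.
#' @export
run_calibrate <- function(features, config = glucopad_config(), out_json = NULL) {
  if (is.character(features)) features <- utils::read.csv(features)
  fr <- config$calibration$fit_range
  sel <- features$concentration_mM >= fr[1] & features$concentration_mM <= fr[2]
  if (sum(sel) < 3L) stop("fewer than 3 images inside the calibration fit range", call. = FALSE)
  fit <- fit_log_calibration(features$concentration_mM[sel],
                             255 - features$gray_intensity[sel],
                             valid_range = config$calibration$valid_range)
  if (all(c("bg_response_mean", "bg_response_sd") %in% names(features))) {
    fit$lod <- compute_lod(fit, mean(features$bg_response_mean),
                           mean(features$bg_response_sd),
                           k = config$calibration$lod_k)
  }
  if (!is.null(out_json)) {
    jsonlite::write_json(fit[c("a", "b", "r_squared", "residual_sd", "lod",
                               "valid_range", "n")],
                         out_json, auto_unbox = TRUE, digits = NA)
  }
  fit
}

#' Stage 4: train the SVR concentration predictor
#'
#' @inheritParams run_calibrate
#' @param out_rds optional path persisting the model (RDS).
#' @return A [train_predictor()] result.
#' @export
run_train <- function(features, config = glucopad_config(), out_rds = NULL) {
  if (is.character(features)) features <- utils::read.csv(features)
  data <- assay_dataset(features[, feature_names()],
                        features$concentration_mM,
                        groups = features$replicate)
  model <- train_predictor(data, kernel = config$train$kernel,
                           cv_folds = config$train$cv_folds,
                           seed = config$seed,
                           train_fraction = config$train$train_fraction)
  if (!is.null(out_rds)) saveRDS(model, out_rds)
  model
}

#' Stage 5: predict concentrations for new images or feature tables
#'
#' @param model a [train_predictor()] result or RDS path.
#' @param input manifest data.frame / CSV with `image_path` (features are
#'   extracted first), or a feature table containing the schema columns.
#' @param config a [glucopad_config()].
#' @param out_csv optional predictions CSV.
#' @return data.frame with `predicted_mM` and `extrapolated`.
#' @export
run_predict <- function(model, input, config = glucopad_config(), out_csv = NULL) {
  if (is.character(model)) model <- readRDS(model)
  if (is.character(input)) input <- utils::read.csv(input, stringsAsFactors = FALSE)
  if (!all(feature_names() %in% names(input))) {
    input <- run_extract(input, config)
  }
  conc <- predict_concentration(model, as.matrix(input[, feature_names()]))
  out <- data.frame(image_path = if ("image_path" %in% names(input))
                      input$image_path else NA_character_,
                    predicted_mM = as.numeric(conc),
                    extrapolated = attr(conc, "extrapolated"))
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Stage 6: shelf-life stability summary
#'
#' Groups the manifest by day, averages the ROI mean response, and
#' reports the percent intensity change from first to last day.
#'
#' @param manifest stability manifest (data.frame or CSV path) with a
#'   `day` column.
#' @param config a [glucopad_config()].
#' @param out_csv optional series CSV.
#' @return A [stability_series()] with attribute
#'   `"percent_intensity_change"`.
#' @export
run_stability <- function(manifest, config = glucopad_config(), out_csv = NULL) {
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    manifest$image_path <- ifelse(file.exists(manifest$image_path),
                                  manifest$image_path,
                                  file.path(base, manifest$image_path))
  }
  days <- sort(unique(manifest$day))
  means <- vapply(days, function(d) {
    paths <- manifest$image_path[manifest$day == d]
    imgs <- lapply(paths, function(p) {
      if (!file.exists(p)) stop(sprintf("manifest references a missing image: %s", p),
                                call. = FALSE)
      preprocess(read_spot_image(p),
                 target_size = config$preprocess$target_size,
                 denoise_kernel = config$preprocess$denoise_kernel)
    })
    masks <- lapply(imgs, segment_spot,
                    shrink_factor = config$segment$shrink_factor,
                    min_area = config$segment$min_area,
                    opening_size = config$segment$opening_size)
    summarize_day(imgs, masks)
  }, numeric(1))
  series <- stability_series(days, means, condition = config$stability$condition)
  attr(series, "percent_intensity_change") <- percent_intensity_change(series)
  if (!is.null(out_csv)) utils::write.csv(as.data.frame(series), out_csv, row.names = FALSE)
  series
}
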