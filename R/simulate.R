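#' Scene parameters for the synthetic spot generator
#'
#' Describes the photographed scene the generator emulates: a circular
#' chromogenic spot (the sample zone of a paper-based analytical device)
#' on paper-colored background, with optional vertical illumination
#' fall-off and pixel-level Gaussian noise on the response scale.
#'
#' @param image_size integer `(height, width)` in pixels.
#' @param spot_center `(row, col)` of the spot center in pixels; defaults
#'   to the image center.
#' @param spot_radius spot radius in pixels; the spot must lie fully
#'   inside the image.
#' @param paper_rgb background (undeveloped paper) color, RGB in `[0, 1]`.
#' @param stain_rgb fully developed chromogen color, RGB in `[0, 1]`.
#'   The default is the warm brown of the triiodide product of the
#'   glucose-oxidase / peroxidase / iodide reaction.
#' @param illum_gradient fractional intensity drop from the top to the
#'   bottom row, in `[0, 0.5]`.  The default `0` keeps the ground-truth
#'   mean response exact; raise it to exercise robustness.
#' @param noise_sd standard deviation of additive Gaussian noise on the
#'   0-255 response scale, applied per pixel (also provides paper grain).
#' @param radial_amplitude relative amplitude of the center-darker radial
#'   development profile inside the spot (mean-preserving).
#' @param seed integer seed; identical seed and parameters give a
#'   bit-identical image.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(image_size = c(192L, 192L),
                         spot_center = NULL,
                         spot_radius = 60,
                         paper_rgb = c(0.96, 0.95, 0.92),
                         stain_rgb = c(0.35, 0.24, 0.08),
                         illum_gradient = 0,
                         noise_sd = 4,
                         radial_amplitude = 0.06,
                         seed = 1L) {
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 8L))
  if (is.null(spot_center)) spot_center <- (image_size + 1) / 2
  stopifnot(length(spot_center) == 2L, length(spot_radius) == 1L, spot_radius > 0)
  stopifnot_rgb01(paper_rgb, "paper_rgb")
  stopifnot_rgb01(stain_rgb, "stain_rgb")
  if (illum_gradient < 0 || illum_gradient > 0.5) {
    stop("illum_gradient must lie in [0, 0.5]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (spot_center[1] - spot_radius < 1 || spot_center[1] + spot_radius > image_size[1] ||
      spot_center[2] - spot_radius < 1 || spot_center[2] + spot_radius > image_size[2]) {
    stop("spot must lie fully inside the image", call. = FALSE)
  }
  structure(list(image_size = image_size, spot_center = as.numeric(spot_center),
                 spot_radius = as.numeric(spot_radius), paper_rgb = as.numeric(paper_rgb),
                 stain_rgb = as.numeric(stain_rgb), illum_gradient = illum_gradient,
                 noise_sd = noise_sd, radial_amplitude = radial_amplitude,
                 seed = as.integer(seed)),
            class = "scene_params")
}

# response intensity (inverted 0-255 gray) of an RGB triple or N x 3 matrix
response_of_rgb <- function(rgb) {
  if (is.matrix(rgb)) 255 * (1 - drop(rgb %*% .lum_wt)) else 255 * (1 - sum(rgb * .lum_wt))
}

#' Simulate one spot image with ground truth
#'
#' Renders a circular spot whose pre-noise mean response over the true
#' disc mask equals the model response at `conc` exactly.  Pixels inside
#' the disc follow a mean-preserving radial development profile mapped
#' through the paper-to-stain color ramp; responses beyond the fully
#' developed stain are rendered by darkening the stain toward black,
#' emulating saturation at molar-range concentrations.  Gaussian response
#' noise and the illumination gradient are applied afterwards.
#'
#' @param model a [response_model()].
#' @param scene a [scene_params()].
#' @param conc concentration in mM (scalar, positive).
#' @return A list with `image` (H x W x 3 array in `[0, 1]`) and `truth`,
#'   a list holding `concentration`, the logical `true_mask`, and the
#'   pre-noise `target_response`.
#' @export
simulate_spot <- function(model, scene, conc) {
  stopifnot(inherits(model, "response_model"), inherits(scene, "scene_params"),
            is_scalar_number(conc))
  target <- evaluate_response(model, conc)

  resp_paper <- response_of_rgb(scene$paper_rgb)
  resp_stain <- response_of_rgb(scene$stain_rgb)
  if (resp_stain <= resp_paper) {
    stop("stain_rgb must be darker than paper_rgb", call. = FALSE)
  }
  if (target < resp_paper) {
    stop(sprintf(paste0("target response %.2f is below the paper background ",
                        "response %.2f: unattainable with this color ramp"),
                 target, resp_paper), call. = FALSE)
  }
  if (target > 255) {
    stop(sprintf("target response %.2f exceeds the ramp maximum 255 (black)",
                 target), call. = FALSE)
  }

  h <- scene$image_size[1]; w <- scene$image_size[2]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  d2 <- (rows - scene$spot_center[1])^2 + (cols - scene$spot_center[2])^2
  mask <- d2 <= scene$spot_radius^2
  npix <- sum(mask)

  # mean-preserving radial profile (darker center), then clip its
  # amplitude so every per-pixel response stays on the attainable ramp
  rel2 <- d2[mask] / scene$spot_radius^2
  prof <- 1 + scene$radial_amplitude * (1 - 2 * rel2)
  prof <- prof / mean(prof)
  r_pix <- target * prof
  s <- 1
  if (max(r_pix) > 255)        s <- min(s, (255 - target) / (max(r_pix) - target))
  if (min(r_pix) < resp_paper) s <- min(s, (target - resp_paper) / (target - min(r_pix)))
  r_pix <- target + s * (r_pix - target)

  # map responses to colors: paper -> stain, then stain -> black
  img <- array(rep(scene$paper_rgb, each = h * w), dim = c(h, w, 3))
  t_lo <- pmin(pmax((r_pix - resp_paper) / (resp_stain - resp_paper), 0), 1)
  u_hi <- pmax((r_pix - resp_stain) / (255 - resp_stain), 0)
  for (k in 1:3) {
    ramp <- (1 - t_lo) * scene$paper_rgb[k] + t_lo * scene$stain_rgb[k]
    ramp <- ramp * (1 - u_hi)
    ch <- img[, , k]
    ch[mask] <- ramp
    img[, , k] <- ch
  }

  withr::with_seed(scene$seed, {
    if (scene$noise_sd > 0) {
      delta <- matrix(stats::rnorm(h * w, 0, scene$noise_sd), h, w)
      img <- img - array(delta, dim = c(h, w, 3)) / 255
    }
  })
  if (scene$illum_gradient > 0) {
    f <- 1 - scene$illum_gradient * (seq_len(h) - 1) / (h - 1)
    img <- img * array(f, dim = c(h, w, 3))
  }
  img <- pmin(pmax(img, 0), 1)

  list(image = img,
       truth = list(concentration = conc, true_mask = mask,
                    target_response = target))
}

#' Simulate a labeled assay dataset
#'
#' One image per (concentration, replicate) pair, with deterministic
#' per-image sub-seeds derived from `seed`.  If `out_dir` is given the
#' images (and optionally the ground-truth masks) are written as 8-bit
#' PNGs and the manifest rows point at those files.
#'
#' @param model a [response_model()].
#' @param scene a [scene_params()]; its `seed` field is overridden per image.
#' @param concentrations positive concentrations in mM.
#' @param replicates replicates per concentration (>= 1).
#' @param seed master seed for the dataset.
#' @param out_dir optional output directory for PNGs and the manifest CSV.
#' @param write_masks also write the ground-truth masks as 0/255 PNGs.
#' @return A list with `manifest` (data.frame: image_path,
#'   concentration_mM, replicate, day, seed), `images` and `truths`
#'   (named lists, in manifest order).
#' @export
simulate_dataset <- function(model, scene, concentrations, replicates = 3L,
                             seed = 1L, out_dir = NULL, write_masks = FALSE) {
  if (length(concentrations) == 0L) stop("empty concentration list", call. = FALSE)
  if (any(concentrations <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (replicates < 1L) stop("replicates must be >= 1", call. = FALSE)

  grid <- expand.grid(replicate = seq_len(replicates),
                      concentration_mM = as.numeric(concentrations),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("concentration_mM", "replicate")]
  n <- nrow(grid)
  sub_seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))

  images <- vector("list", n); truths <- vector("list", n)
  paths <- character(n)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n)) {
    sc <- scene; sc$seed <- sub_seeds[i]
    sim <- simulate_spot(model, sc, grid$concentration_mM[i])
    images[[i]] <- sim$image; truths[[i]] <- sim$truth
    nm <- sprintf("spot_c%s_r%d.png",
                  gsub("[^0-9a-zA-Z]", "p", format(grid$concentration_mM[i])),
                  grid$replicate[i])
    if (!is.null(out_dir)) {
      paths[i] <- file.path(out_dir, nm)
      write_spot_png(sim$image, paths[i])
      if (write_masks) {
        write_mask_png(sim$truth$true_mask,
                       file.path(out_dir, sub("\\.png$", "_mask.png", nm)))
      }
    } else {
      paths[i] <- nm
    }
  }
  manifest <- data.frame(image_path = paths,
                         concentration_mM = grid$concentration_mM,
                         replicate = grid$replicate,
                         day = 0L, seed = sub_seeds,
                         stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    # CSV carries paths relative to its own location so runs into
    # different directories stay byte-identical
    rel <- manifest; rel$image_path <- basename(rel$image_path)
    utils::write.csv(rel, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, images = images, truths = truths)
}

#' Simulate a shelf-life stability series
#'
#' Emulates stored pads losing chromogenic activity: the target response
#' at day `d` is the day-zero response scaled by a linear monotone decay
#' reaching `1 - decay_fraction_at_end` of the initial value on the last
#' day.
#'
#' @inheritParams simulate_dataset
#' @param conc test concentration in mM (fixed across days).
#' @param days ascending day indices; the first day carries no decay.
#' @param decay_fraction_at_end fraction of response lost by the final
#'   day, in `[0, 1)`.
#' @param replicates images per day.
#' @return As [simulate_dataset()], with the manifest `day` column filled
#'   and a `target_response` column giving the decayed ground truth.
#' @export
simulate_stability_series <- function(model, scene, conc, days,
                                      decay_fraction_at_end = 0.62,
                                      replicates = 3L, seed = 1L,
                                      out_dir = NULL) {
  if (decay_fraction_at_end < 0 || decay_fraction_at_end >= 1) {
    stop("decay_fraction_at_end must lie in [0, 1)", call. = FALSE)
  }
  if (length(days) < 1L || is.unsorted(days, strictly = TRUE)) {
    stop("days must be strictly ascending", call. = FALSE)
  }
  target0 <- evaluate_response(model, conc)
  span <- if (length(days) > 1L) days[length(days)] - days[1] else 1
  factors <- 1 - decay_fraction_at_end * (days - days[1]) / span

  n <- length(days) * replicates
  images <- vector("list", n); truths <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  i <- 0L
  for (di in seq_along(days)) {
    # decayed pads are emulated by lowering the effective concentration so
    # that the target response is scaled by the decay factor
    conc_eff <- exp((target0 * factors[di] - model$b) / model$a)
    for (r in seq_len(replicates)) {
      i <- i + 1L
      sc <- scene; sc$seed <- derive_seed(seed, i)
      sim <- simulate_spot(model, sc, conc_eff)
      sim$truth$concentration <- conc  # nominal assay concentration
      sim$truth$target_response <- target0 * factors[di]
      images[[i]] <- sim$image; truths[[i]] <- sim$truth
      nm <- sprintf("stab_d%03d_r%d.png", days[di], r)
      path <- if (!is.null(out_dir)) file.path(out_dir, nm) else nm
      if (!is.null(out_dir)) write_spot_png(sim$image, path)
      rows[[i]] <- data.frame(image_path = path, concentration_mM = conc,
                              replicate = r, day = days[di], seed = sc$seed,
                              target_response = target0 * factors[di],
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    rel <- manifest; rel$image_path <- basename(rel$image_path)
    utils::write.csv(rel, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  }
  list(manifest = manifest, images = images, truths = truths)
}
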