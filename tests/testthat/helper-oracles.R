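# Independent brute-force oracles used to pin expected values.

# naive central-moment statistics by explicit summation
oracle_channel_stats <- function(x) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  if (m2 < 1e-12) return(c(mean = mu, skewness = 0, kurtosis = 3))
  c(mean = mu, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2)
}

# GLCM by explicit per-pixel pair enumeration
oracle_glcm <- function(gray, mask = NULL, Ng = 8, offset = c(0, 1),
                        symmetric = TRUE) {
  h <- nrow(gray); w <- ncol(gray)
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  q <- pmin(floor(gray * Ng / 256), Ng - 1)
  p <- matrix(0, Ng, Ng)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      r2 <- r + offset[1]; c2 <- c + offset[2]
      if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w && mask[r, c] && mask[r2, c2]) {
        i <- q[r, c] + 1; j <- q[r2, c2] + 1
        p[i, j] <- p[i, j] + 1
        if (symmetric) p[j, i] <- p[j, i] + 1
      }
    }
  }
  p / sum(p)
}

# GLCM metrics by direct double loops over the matrix
oracle_glcm_metrics <- function(p, gray_roi) {
  Ng <- nrow(p)
  contrast <- 0; energy <- 0; homog <- 0; entropy <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    mu_i <- mu_i + (i - 1) * p[i, j]
    mu_j <- mu_j + (j - 1) * p[i, j]
  }
  var_i <- 0; var_j <- 0; cov_ij <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    contrast <- contrast + (i - j)^2 * p[i, j]
    energy <- energy + p[i, j]^2
    homog <- homog + p[i, j] / (1 + abs(i - j))
    if (p[i, j] > 0) entropy <- entropy - p[i, j] * log2(p[i, j])
    var_i <- var_i + (i - 1 - mu_i)^2 * p[i, j]
    var_j <- var_j + (j - 1 - mu_j)^2 * p[i, j]
    cov_ij <- cov_ij + (i - 1 - mu_i) * (j - 1 - mu_j) * p[i, j]
  }
  corr <- if (sqrt(var_i * var_j) < 1e-12) 1 else cov_ij / sqrt(var_i * var_j)
  c(contrast = contrast, correlation = corr, energy = energy,
    homogeneity = homog, entropy = entropy, intensity = mean(gray_roi))
}

# shared small scenes so tests stay fast
quiet_scene <- function(...) {
  scene_params(image_size = c(96L, 96L), spot_radius = 28, noise_sd = 0,
               radial_amplitude = 0, ...)
}

noisy_scene <- function(...) {
  scene_params(image_size = c(96L, 96L), spot_radius = 28, ...)
}

# ground-truth disc mask shrunk like segment_spot's ROI
shrunk_truth_mask <- function(scene, shrink = 0.8) {
  h <- scene$image_size[1]; w <- scene$image_size[2]
  rr <- matrix(seq_len(h), h, w); cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - scene$spot_center[1])^2 + (cc - scene$spot_center[2])^2 <=
    (shrink * scene$spot_radius)^2
}
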