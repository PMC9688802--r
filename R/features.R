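# 51-entry chemometric descriptor: mean/skewness/kurtosis on each of the
# 15 chromatic channels (45 values) plus six GLCM texture/intensity
# metrics computed on the standard 0-255 gray channel.

#' Moment statistics of a pixel sample
#'
#' Population central moments: skewness `m3 / m2^1.5` and non-excess
#' kurtosis `m4 / m2^2` (Gaussian = 3).  A (numerically) constant sample
#' returns skewness 0 and kurtosis 3.
#'
#' @param values numeric sample (>= 1 value).
#' @return Named vector `(mean, skewness, kurtosis)`.
#' @export
channel_stats <- function(values) {
  n <- length(values)
  if (n == 0L) stop("empty sample", call. = FALSE)
  mu <- mean(values)
  d <- values - mu
  m2 <- mean(d^2)
  if (m2 < 1e-12) return(c(mean = mu, skewness = 0, kurtosis = 3))
  c(mean = mu,
    skewness = mean(d^3) / m2^1.5,
    kurtosis = mean(d^4) / m2^2)
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurring quantized gray levels at a fixed pixel offset,
#' restricted to pixel pairs that both lie inside the mask.  Gray values
#' in `[0, 255]` are quantized by uniform binning into `Ng` levels.  With
#' `symmetric = TRUE` each pair is accumulated in both orders; the matrix
#' is normalized to sum to 1.
#'
#' @param gray `H x W` matrix of gray values in `[0, 255]`.
#' @param mask logical `H x W` matrix (or a `roi_mask`); `NULL` uses all
#'   pixels.
#' @param Ng number of gray levels (>= 2).
#' @param offset integer `(drow, dcol)` spatial relationship.
#' @param symmetric accumulate both pair orders.
#' @return Object of class `glcm_matrix`: list with `p` (Ng x Ng,
#'   sums to 1), `Ng`, `offset`, `symmetric`.
#' @export
compute_glcm <- function(gray, mask = NULL, Ng = 8L, offset = c(0L, 1L),
                         symmetric = TRUE) {
  stopifnot(is.matrix(gray), Ng >= 2L, length(offset) == 2L)
  if (inherits(mask, "roi_mask")) mask <- mask$mask
  if (is.null(mask)) mask <- matrix(TRUE, nrow(gray), ncol(gray))
  stopifnot(all(dim(mask) == dim(gray)))
  if (!any(mask)) stop("ROI is empty", call. = FALSE)

  q <- pmin(floor(gray * Ng / 256), Ng - 1L)  # levels 0 .. Ng-1
  h <- nrow(gray); w <- ncol(gray)
  dr <- as.integer(offset[1]); dc <- as.integer(offset[2])

  r1 <- seq_len(h); c1 <- seq_len(w)
  r1 <- r1[r1 + dr >= 1L & r1 + dr <= h]
  c1 <- c1[c1 + dc >= 1L & c1 + dc <= w]
  if (length(r1) == 0L || length(c1) == 0L) {
    stop("DegenerateGlcm: offset larger than image", call. = FALSE)
  }
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  ok <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
  if (!any(ok)) stop("DegenerateGlcm: no valid pixel pairs", call. = FALSE)

  counts <- table(factor(a[ok], levels = 0:(Ng - 1L)),
                  factor(b[ok], levels = 0:(Ng - 1L)))
  p <- matrix(as.numeric(counts), Ng, Ng)
  if (symmetric) p <- p + t(p)
  p <- p / sum(p)
  structure(list(p = p, Ng = as.integer(Ng), offset = c(dr, dc),
                 symmetric = symmetric),
            class = "glcm_matrix")
}

#' Texture and intensity metrics from a GLCM
#'
#' Haralick-style metrics of the co-occurrence distribution `p(i, j)`:
#' contrast, correlation (defined as 1 for a degenerate single-level
#' distribution), energy (angular second moment), homogeneity (inverse
#' difference), Shannon entropy in bits, plus the mean of the unquantized
#' gray ROI as overall intensity.
#'
#' @param glcm a [compute_glcm()] result.
#' @param gray_roi unquantized gray values of the ROI pixels (for the
#'   intensity metric).
#' @return Named vector `(contrast, correlation, energy, homogeneity,
#'   entropy, intensity)`.
#' @export
glcm_metrics <- function(glcm, gray_roi) {
  stopifnot(inherits(glcm, "glcm_matrix"))
  p <- glcm$p
  lev <- seq_len(glcm$Ng) - 1
  i <- matrix(lev, glcm$Ng, glcm$Ng)
  j <- t(i)
  pi_ <- rowSums(p); pj_ <- colSums(p)
  mu_i <- sum(lev * pi_); mu_j <- sum(lev * pj_)
  sd_i <- sqrt(sum((lev - mu_i)^2 * pi_)); sd_j <- sqrt(sum((lev - mu_j)^2 * pj_))
  corr <- if (sd_i * sd_j < 1e-12) 1 else
    sum((i - mu_i) * (j - mu_j) * p) / (sd_i * sd_j)
  nz <- p > 0
  c(contrast = sum((i - j)^2 * p),
    correlation = corr,
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))),
    entropy = -sum(p[nz] * log2(p[nz])),
    intensity = mean(gray_roi))
}

#' Canonical 51-name feature schema
#'
#' 45 moment features in channel-major order (`R_mean, R_skew, R_kurt,
#' ..., Q_kurt`) followed by the six GLCM texture/intensity names.
#'
#' @return Character vector of length 51.
#' @export
feature_names <- function() {
  moments <- as.vector(t(outer(.chromatic_channels,
                               c("mean", "skew", "kurt"), paste, sep = "_")))
  c(moments, "glcm_contrast", "glcm_correlation", "glcm_energy",
    "glcm_homogeneity", "glcm_entropy", "gray_intensity")
}

#' Extract the 51-entry feature vector of one ROI
#'
#' For each of the 15 chromatic channels (R, G, B, H, S, V, L*, a*, b*,
#' X, Y, Z, NTSC luma, I, Q) the mean, skewness and kurtosis of the ROI
#' pixel distribution are computed (45 values), followed by the six GLCM
#' texture/intensity metrics of the standard gray channel.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask a [segment_spot()] result or logical `H x W` matrix.
#' @param Ng,offset,symmetric GLCM parameters, see [compute_glcm()].
#' @return Named numeric vector of length 51 (schema
#'   [feature_names()]).
#' @export
extract_features <- function(image, mask, Ng = 8L, offset = c(0L, 1L),
                             symmetric = TRUE) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  pixels <- extract_roi_pixels(image, m)
  stack <- channel_stack(pixels)

  moments <- unlist(lapply(.chromatic_channels, function(ch) {
    s <- channel_stats(stack[, ch])
    stats::setNames(s, paste(ch, c("mean", "skew", "kurt"), sep = "_"))
  }))

  gray_full <- 255 * (image[, , 1] * .lum_wt[1] + image[, , 2] * .lum_wt[2] +
                        image[, , 3] * .lum_wt[3])
  glcm <- compute_glcm(gray_full, m, Ng = Ng, offset = offset,
                       symmetric = symmetric)
  tex <- glcm_metrics(glcm, gray_full[m])
  names(tex) <- c("glcm_contrast", "glcm_correlation", "glcm_energy",
                  "glcm_homogeneity", "glcm_entropy", "gray_intensity")

  out <- c(moments, tex)
  stopifnot(length(out) == 51L, identical(names(out), feature_names()))
  out
}
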