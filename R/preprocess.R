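#' Preprocess a raw spot photograph
#'
#' Brings an image to the standard analysis geometry and suppresses
#' impulsive sensor noise: the image is center-cropped to the target
#' aspect ratio, rescaled to `target_size`, and median-filtered per
#' channel.  A kernel of 1 disables filtering.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param target_size integer `(height, width)` after resizing; a scalar
#'   is used for both.
#' @param denoise_kernel odd median-filter window width in pixels
#'   (1 = no filtering).
#' @return Preprocessed `H x W x 3` array in `[0, 1]`.
#' @export
preprocess <- function(image, target_size = c(256L, 256L), denoise_kernel = 3L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("input must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (any(dim(image)[1:2] == 0L)) stop("zero-size image", call. = FALSE)
  if (denoise_kernel < 1L || denoise_kernel %% 2L == 0L) {
    stop("denoise_kernel must be an odd integer >= 1", call. = FALSE)
  }
  if (length(target_size) == 1L) target_size <- c(target_size, target_size)
  target_size <- as.integer(target_size)

  h <- dim(image)[1]; w <- dim(image)[2]
  # center-crop to the target aspect ratio so resizing does not distort
  aspect <- target_size[2] / target_size[1]
  if (abs(w / h - aspect) > 1e-9) {
    if (w / h > aspect) {
      w2 <- max(1L, as.integer(round(h * aspect)))
      off <- (w - w2) %/% 2L
      image <- image[, (off + 1L):(off + w2), , drop = FALSE]
    } else {
      h2 <- max(1L, as.integer(round(w / aspect)))
      off <- (h - h2) %/% 2L
      image <- image[(off + 1L):(off + h2), , , drop = FALSE]
    }
  }

  e <- as_ebimage(image)
  if (!all(dim(image)[1:2] == target_size)) {
    e <- EBImage::resize(e, w = target_size[2], h = target_size[1])
  }
  if (denoise_kernel > 1L) {
    e <- EBImage::medianFilter(e, size = (denoise_kernel - 1L) %/% 2L)
  }
  out <- pmin(pmax(from_ebimage(e), 0), 1)
  attr(out, "source_path") <- attr(image, "source_path")
  out
}

#' Segment the assay spot and fit a disc ROI
#'
#' Finds the region of the image chromatically distinct from the modal
#' paper background: per-pixel Euclidean RGB distance to the robust
#' background color (median of the border frame), Otsu-thresholded, then
#' cleaned by morphological opening.  The largest connected component is
#' summarized by a fitted disc (centroid and equivalent-area radius), and
#' the returned mask is that disc shrunk to `shrink_factor * radius` so
#' rim and coffee-ring artifacts are excluded from analysis.
#'
#' The chromatic criterion makes the segmentation robust to moderate
#' global brightness changes: the background estimate shifts with the
#' image, and Otsu adapts the threshold.
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param shrink_factor fraction of the fitted radius kept, in `(0, 1]`.
#' @param min_area minimum component area in pixels before a spot is
#'   accepted.
#' @param opening_size diameter of the disc brush used for morphological
#'   opening.
#' @return An object of class `roi_mask`: list with logical `mask`,
#'   fitted `center` `(row, col)` and `radius` in pixels (pre-shrink).
#' @export
segment_spot <- function(image, shrink_factor = 0.8, min_area = 50L,
                         opening_size = 5L) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L) {
    stop("input must be an H x W x 3 RGB array", call. = FALSE)
  }
  if (shrink_factor <= 0 || shrink_factor > 1) {
    stop("shrink_factor must lie in (0, 1]", call. = FALSE)
  }
  h <- dim(image)[1]; w <- dim(image)[2]

  # modal background from the border frame (robust to the spot itself)
  bw <- max(2L, round(min(h, w) * 0.05))
  border <- rbind(
    apply(image[c(seq_len(bw), (h - bw + 1L):h), , , drop = FALSE], 3, c),
    apply(image[, c(seq_len(bw), (w - bw + 1L):w), , drop = FALSE], 3, c))
  bg <- apply(border, 2, stats::median)

  dist <- sqrt((image[, , 1] - bg[1])^2 + (image[, , 2] - bg[2])^2 +
                 (image[, , 3] - bg[3])^2)
  dmax <- max(dist)
  if (dmax < 1e-8) stop("NoSpotFound: image is uniform", call. = FALSE)
  dn <- dist / dmax
  thr <- EBImage::otsu(EBImage::Image(t(dn)), range = c(0, 1))
  bin <- EBImage::Image(t(dn > thr))
  bin <- EBImage::opening(bin, EBImage::makeBrush(opening_size, shape = "disc"))
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab < 1L) stop("NoSpotFound: no component above threshold", call. = FALSE)
  areas <- tabulate(as.integer(lab[lab > 0]), nbins = nlab)
  best <- which.max(areas)
  if (areas[best] < min_area) {
    stop(sprintf("NoSpotFound: largest component has %d px (< %d)",
                 areas[best], as.integer(min_area)), call. = FALSE)
  }
  comp <- t(EBImage::imageData(lab)) == best  # back to (row, col)

  idx <- which(comp, arr.ind = TRUE)
  center <- colMeans(idx)                      # (row, col)
  radius <- sqrt(areas[best] / pi)

  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- (rows - center[1])^2 + (cols - center[2])^2 <=
    (shrink_factor * radius)^2
  if (!any(mask)) stop("NoSpotFound: shrunk disc is empty", call. = FALSE)

  structure(list(mask = mask, center = unname(center), radius = radius,
                 shrink_factor = shrink_factor),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("ROI disc: center (%.1f, %.1f), radius %.1f px, %d px at shrink %.2f\n",
              x$center[1], x$center[2], x$radius, sum(x$mask), x$shrink_factor))
  invisible(x)
}

#' Extract ROI pixels
#'
#' Pure selection of the masked pixels, returned in row-major scan order
#' (top-left to bottom-right).
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param mask a [segment_spot()] result or a logical `H x W` matrix.
#' @return `N x 3` matrix of RGB values, columns named R, G, B.
#' @export
extract_roi_pixels <- function(image, mask) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!all(dim(m) == dim(image)[1:2])) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (!any(m)) stop("empty mask", call. = FALSE)
  ord <- mask_indices_rowmajor(m)
  out <- cbind(R = image[, , 1][ord], G = image[, , 2][ord], B = image[, , 3][ord])
  out
}
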