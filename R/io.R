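# image reading/writing: internal arrays are H x W x 3 in [0, 1],
# indexed (row, col) from the top-left corner

#' Read a spot photograph
#'
#' Reads a PNG or JPEG into the package's internal representation, an
#' `H x W x 3` numeric array with values in `[0, 1]`.  Grayscale input is
#' expanded to three channels; an alpha channel is dropped.
#'
#' @param path file path to a PNG or JPEG image.
#' @return `H x W x 3` array in `[0, 1]` with attribute `source_path`.
#' @export
read_spot_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("image file not found: %s", path), call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
  } else {
    # EBImage stores (x = col, y = row); transpose into (row, col, channel)
    e <- EBImage::readImage(path)
    d <- dim(e)
    a <- if (length(d) == 2L) t(EBImage::imageData(e)) else
      aperm(EBImage::imageData(e), c(2L, 1L, 3L))
  }
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  a <- pmin(pmax(a, 0), 1)
  attr(a, "source_path") <- path
  a
}

#' Write a spot image as an 8-bit PNG
#'
#' @param image `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spot_png <- function(image, path) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask logical matrix (or `roi_mask`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

# convert internal (row, col, channel) array to an EBImage Color image
as_ebimage <- function(image) {
  EBImage::Image(aperm(image, c(2L, 1L, 3L)), colormode = "Color")
}

from_ebimage <- function(e) {
  d <- dim(e)
  if (length(d) == 2L) t(EBImage::imageData(e)) else aperm(EBImage::imageData(e), c(2L, 1L, 3L))
}
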