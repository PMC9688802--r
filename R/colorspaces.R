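# Color-space conversions feeding the chemometric feature set.  All
# transforms are pixelwise and deterministic; inputs are RGB in [0, 1].

# NTSC (FCC) luma/chroma matrix, rounded to 4 decimals.  Both chroma rows
# sum to zero, so the attainable extrema over the RGB cube are exactly
# +/-0.5959 for I (pure red / cyan) and +/-0.5229 for Q (magenta / green).
.yiq_matrix <- matrix(c(0.299,  0.587,  0.114,
                        0.5959, -0.2746, -0.3213,
                        0.2115, -0.5229,  0.3114),
                      nrow = 3, byrow = TRUE,
                      dimnames = list(c("Yn", "I", "Q"), c("R", "G", "B")))

as_rgb_matrix <- function(rgb) {
  m <- if (is.matrix(rgb)) rgb else matrix(rgb, ncol = 3)
  if (ncol(m) != 3L) stop("rgb must have three components", call. = FALSE)
  stopifnot_rgb01(m)
  m
}

#' RGB to NTSC luma/chroma (YIQ)
#'
#' Linear transform of RGB into luma `Yn` (picture brightness, `[0, 1]`),
#' in-phase `I` (orange-blue axis, `[-0.5959, 0.5959]`) and quadrature
#' `Q` (purple-green axis, `[-0.5229, 0.5229]`).
#'
#' @param rgb RGB triple or `N x 3` matrix, components in `[0, 1]`.
#' @return `N x 3` matrix with columns Yn, I, Q (a vector for one pixel).
#' @export
rgb_to_yiq <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  out <- m %*% t(.yiq_matrix)
  colnames(out) <- rownames(.yiq_matrix)
  if (!is.matrix(rgb)) out <- drop(out)
  out
}

#' RGB to HSV (hexcone model)
#'
#' Hue is reported in degrees `[0, 360)`, with the achromatic degenerate
#' case assigned hue 0.
#'
#' @inheritParams rgb_to_yiq
#' @return `N x 3` matrix with columns H, S, V (a vector for one pixel).
#' @export
rgb_to_hsv_deg <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  hsv <- t(grDevices::rgb2hsv(t(m), maxColorValue = 1))
  out <- cbind(H = hsv[, 1] * 360, S = hsv[, 2], V = hsv[, 3])
  out[out[, "H"] >= 360, "H"] <- 0
  if (!is.matrix(rgb)) out <- drop(out)
  out
}

#' RGB to CIE XYZ and CIELAB
#'
#' sRGB primaries with the D65 white point: channels are gamma-expanded,
#' mapped linearly to XYZ (white Y = 1), and XYZ to L*a*b* relative to
#' D65.
#'
#' @inheritParams rgb_to_yiq
#' @return `N x 6` matrix with columns X, Y, Z, L, a, b (a vector for one
#'   pixel).
#' @export
rgb_to_xyz_lab <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  xyz <- grDevices::convertColor(m, from = "sRGB", to = "XYZ")
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  out <- cbind(X = xyz[, 1], Y = xyz[, 2], Z = xyz[, 3],
               L = lab[, 1], a = lab[, 2], b = lab[, 3])
  if (!is.matrix(rgb)) out <- drop(out)
  out
}

#' RGB to the two 0-255 gray variants
#'
#' `gray_standard` is the usual luminance gray (`255` = white);
#' `response` is its inversion (`0` = white paper, `255` = black), the
#' scale on which a more developed assay color reads higher.
#'
#' @inheritParams rgb_to_yiq
#' @return `N x 2` matrix with columns gray_standard, response (a vector
#'   for one pixel).
#' @export
rgb_to_gray <- function(rgb) {
  m <- as_rgb_matrix(rgb)
  g <- 255 * drop(m %*% .lum_wt)
  out <- cbind(gray_standard = g, response = 255 - g)
  if (!is.matrix(rgb)) out <- drop(out)
  out
}

# canonical channel order of the feature schema
.chromatic_channels <- c("R", "G", "B", "H", "S", "V", "L", "a", "b",
                         "X", "Y", "Z", "Yn", "I", "Q")

#' Build the full channel stack for a set of pixels
#'
#' @param pixels `N x 3` RGB matrix in `[0, 1]`.
#' @return `N x 17` matrix: the 15 chromatic channels
#'   (R, G, B, H, S, V, L, a, b, X, Y, Z, Yn, I, Q) followed by the two
#'   gray variants (gray_standard, response).
#' @export
channel_stack <- function(pixels) {
  m <- as_rgb_matrix(pixels)
  hsv <- rgb_to_hsv_deg(m)
  xyzlab <- rgb_to_xyz_lab(m)
  yiq <- rgb_to_yiq(m)
  gray <- rgb_to_gray(m)
  out <- cbind(R = m[, 1], G = m[, 2], B = m[, 3],
               H = hsv[, "H"], S = hsv[, "S"], V = hsv[, "V"],
               L = xyzlab[, "L"], a = xyzlab[, "a"], b = xyzlab[, "b"],
               X = xyzlab[, "X"], Y = xyzlab[, "Y"], Z = xyzlab[, "Z"],
               Yn = yiq[, "Yn"], I = yiq[, "I"], Q = yiq[, "Q"],
               gray_standard = gray[, "gray_standard"],
               response = gray[, "response"])
  out
}
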