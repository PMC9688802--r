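# internal helpers shared across modules

#' @importFrom withr with_seed
NULL

# Deterministic sub-seed derivation: one user-facing seed fans out to
# per-image / per-stage streams.  Kept inside 32-bit signed range.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647L)
}

# Luminance weights used for the 0-255 gray scale and its inverted
# "response" variant (large = dark, i.e. more developed color).
.lum_wt <- c(0.299, 0.587, 0.114)

stopifnot_rgb01 <- function(x, what = "rgb") {
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s components must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# row-major linear ordering of TRUE cells of a logical matrix
mask_indices_rowmajor <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
}
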