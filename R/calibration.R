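#' Fit the logarithmic calibration curve
#'
#' Ordinary least squares of the response intensity on the natural log of
#' concentration, `y = a ln(x) + b` — the linearization that reproduces
#' the logarithmic dose-response exactly, so no iterative fitting is
#' needed.
#'
#' @param concentration concentrations in mM (> 0, >= 3 distinct values).
#' @param response response intensities (0-255 scale).
#' @param valid_range concentration range (mM) within which the curve is
#'   considered interpolating; predictions outside are flagged.  The
#'   default upper end reflects the instability of the developed color
#'   above 14 mM.
#' @return Object of class `calibration_fit`: `a` (slope per ln(mM)),
#'   `b` (intercept), `r_squared`, `residual_sd`, `lod` (NA until
#'   [compute_lod()] is used), `valid_range`, `n`.
#' @examples
#' x <- c(0.5, 1, 2, 5, 8, 11, 14, 17, 20)
#' fit <- fit_log_calibration(x, 36.958 * log(x) + 61.367)
#' fit$a; fit$r_squared
#' @export
fit_log_calibration <- function(concentration, response,
                                valid_range = c(0.5, 14)) {
  if (length(concentration) != length(response)) {
    stop("concentration and response lengths differ", call. = FALSE)
  }
  if (anyNA(concentration) || any(concentration <= 0)) {
    stop("concentrations must be strictly positive", call. = FALSE)
  }
  if (length(unique(concentration)) < 3L) {
    stop("need at least 3 distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(response ~ log(concentration))
  a <- unname(stats::coef(fit)[2]); b <- unname(stats::coef(fit)[1])
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((response - mean(response))^2)
  r2 <- if (ss_tot < 1e-12) 0 else 1 - ss_res / ss_tot
  n <- length(response)
  structure(list(a = a, b = b, r_squared = r2,
                 residual_sd = sqrt(ss_res / (n - 2)),
                 lod = NA_real_, valid_range = as.numeric(valid_range), n = n),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: y = %.3f * ln(x) + %.3f  (R^2 = %.3f, s = %.2f, n = %d)\n",
              x$a, x$b, x$r_squared, x$residual_sd, x$n))
  if (is.finite(x$lod)) cat(sprintf("LOD: %.3f mM\n", x$lod))
  cat(sprintf("Valid range: %.2f - %.2f mM\n", x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

#' Invert the calibration: response to concentration
#'
#' @param fit a [fit_log_calibration()] result (slope must be nonzero).
#' @param response response intensities.
#' @return Concentrations in mM, with a logical attribute
#'   `"extrapolated"` marking values outside `fit$valid_range`.
#' @export
invert_calibration <- function(fit, response) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (abs(fit$a) < 1e-12) stop("calibration slope is zero: not invertible", call. = FALSE)
  conc <- exp((response - fit$b) / fit$a)
  attr(conc, "extrapolated") <- conc < fit$valid_range[1] | conc > fit$valid_range[2]
  conc
}

#' Limit of detection via the 3.3-sigma signal-domain convention
#'
#' Because the logarithmic model has no constant slope in concentration
#' space, the decision level is formed in signal space as
#' `blank_mean + 3.3 * blank_sd` and mapped through the inverse
#' calibration.
#'
#' @param fit a [fit_log_calibration()] result with positive slope.
#' @param blank_mean mean blank response.
#' @param blank_sd standard deviation of blank responses (>= 0).
#' @param k multiplier of the blank standard deviation (3.3 by
#'   convention; use 3 for the laxer variant).
#' @return LOD in mM.
#' @export
compute_lod <- function(fit, blank_mean, blank_sd, k = 3.3) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (blank_sd < 0) stop("blank_sd must be >= 0", call. = FALSE)
  if (fit$a <= 0) stop("LOD requires a positive calibration slope", call. = FALSE)
  y_lod <- blank_mean + k * blank_sd
  if (y_lod < 0 || y_lod > 255) {
    stop(sprintf("decision level %.2f lies outside the attainable response range [0, 255]",
                 y_lod), call. = FALSE)
  }
  as.numeric(exp((y_lod - fit$b) / fit$a))
}
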