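#' Logarithmic response model of the colorimetric assay
#'
#' The developed color of a chromogenic glucose spot, read out on an
#' inverted 0-255 gray scale (0 = white paper, 255 = black), follows a
#' logarithmic dose-response over the working range:
#' \deqn{y = a \,\ln(x) + b}
#' with `x` the glucose concentration in mM and `y` the response intensity.
#' The default coefficients `a = 36.958`, `b = 61.367` are the calibration
#' used throughout the synthetic generator, so that `x = 1` mM yields
#' exactly `b` before clamping.
#'
#' @param a slope, response units per ln(mM).
#' @param b intercept, response units on the 0-255 scale.
#' @param clamp_lo,clamp_hi bounds to which the evaluated response is
#'   clamped (the 8-bit display range by default).
#'
#' @return An object of class `response_model`.
#' @examples
#' m <- response_model()
#' evaluate_response(m, 1)    # == b
#' evaluate_response(m, 500)  # clamped to 255
#' @export
response_model <- function(a = 36.958, b = 61.367, clamp_lo = 0, clamp_hi = 255) {
  stopifnot(is_scalar_number(a), is_scalar_number(b),
            is_scalar_number(clamp_lo), is_scalar_number(clamp_hi))
  if (clamp_lo >= clamp_hi) stop("clamp_lo must be < clamp_hi", call. = FALSE)
  structure(list(a = a, b = b, clamp_lo = clamp_lo, clamp_hi = clamp_hi),
            class = "response_model")
}

#' @export
print.response_model <- function(x, ...) {
  cat(sprintf("Logarithmic response model: y = %.3f * ln(x) + %.3f, clamped to [%g, %g]\n",
              x$a, x$b, x$clamp_lo, x$clamp_hi))
  invisible(x)
}

#' Evaluate the response model at given concentrations
#'
#' @param model a [response_model()].
#' @param conc concentration(s) in mM; must be strictly positive.
#' @return Response intensities on the model's clamped scale.
#' @export
evaluate_response <- function(model, conc) {
  stopifnot(inherits(model, "response_model"))
  if (length(conc) == 0L || anyNA(conc) || any(conc <= 0)) {
    stop("concentration must be strictly positive (log model domain)", call. = FALSE)
  }
  pmin(pmax(model$a * log(conc) + model$b, model$clamp_lo), model$clamp_hi)
}
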