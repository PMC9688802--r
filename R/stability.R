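# Shelf-life analysis: per-day mean response and percent intensity change.

#' Mean response of the images taken on one day
#'
#' Each image contributes the mean of the response channel (inverted
#' 0-255 gray) over its ROI; the per-image means are averaged.
#'
#' @param images list of `H x W x 3` arrays in `[0, 1]`.
#' @param masks list of [segment_spot()] results or logical matrices,
#'   one per image (a single mask is recycled).
#' @return Mean response (scalar).
#' @export
summarize_day <- function(images, masks) {
  if (length(images) == 0L) stop("no images for this day", call. = FALSE)
  if (!is.list(masks) || inherits(masks, "roi_mask")) masks <- list(masks)
  if (length(masks) == 1L) masks <- rep(masks, length(images))
  stopifnot(length(masks) == length(images))
  per_image <- mapply(function(img, msk) {
    px <- extract_roi_pixels(img, msk)
    mean(rgb_to_gray(px)[, "response"])
  }, images, masks)
  mean(per_image)
}

#' Assemble a stability series from per-day summaries
#'
#' @param days ascending day indices.
#' @param mean_response per-day mean responses (same length).
#' @param condition free-text storage condition label (e.g.
#'   `"trehalose/4C"`).
#' @return Object of class `stability_series` (a data.frame with
#'   columns condition, day, mean_response).
#' @export
stability_series <- function(days, mean_response, condition = "default") {
  if (length(days) != length(mean_response)) stop("length mismatch", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE)) stop("days must be ascending", call. = FALSE)
  if (any(!is.finite(mean_response))) stop("responses must be finite", call. = FALSE)
  structure(data.frame(condition = condition, day = days,
                       mean_response = mean_response),
            class = c("stability_series", "data.frame"))
}

#' Percent intensity change over a stability series
#'
#' `100 * (1 - last / first)` on the response scale: positive values mean
#' the developed color faded over storage, negative values mean it
#' intensified.
#'
#' @param series a [stability_series()] (or data.frame with `day` and
#'   `mean_response` columns covering >= 2 days).
#' @return Percent change (scalar).
#' @export
percent_intensity_change <- function(series) {
  stopifnot(all(c("day", "mean_response") %in% names(series)))
  s <- series[order(series$day), ]
  if (nrow(s) < 2L) stop("need at least 2 days", call. = FALSE)
  first <- s$mean_response[1]; last <- s$mean_response[nrow(s)]
  if (first <= 0) stop("first-day response must be positive", call. = FALSE)
  100 * (1 - last / first)
}
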