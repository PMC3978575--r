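# Per-image dense/fatty thresholding and density measurement. The threshold
# is found independently for every mammogram from its own breast histogram:
# no standardisation across images is needed or performed.

#' Compute the optimal dense/fatty intensity threshold
#'
#' Scans every intensity present within the breast and returns the cut
#' maximising the between-class criterion
#' \deqn{J(t) = (S_0 n_1 - S_1 n_0)^2 / (n_0 n_1),}
#' where class 0 holds breast pixels with intensity \eqn{\le t} (count
#' \eqn{n_0}, intensity sum \eqn{S_0}) and class 1 the strictly brighter
#' pixels. \eqn{J} is algebraically \eqn{n_0 n_1 (\mu_0 - \mu_1)^2}, a
#' positive rescaling of the classic between-class variance, so the
#' maximiser is the between-class-variance maximiser; the brighter class is
#' the dense tissue by construction. Ties take the smallest threshold. The
#' result is deterministic for a given image and depends on no other image.
#'
#' A constant breast has no dense/fatty contrast: the maximum breast
#' intensity is returned with `degenerate = TRUE` (giving dense area 0), so
#' this stage never fails on a successfully segmented breast.
#'
#' @param image A preprocessed [grey_image].
#' @param mask A [breast_mask] with the image's dimensions.
#' @return List with `threshold` (intensity), `degenerate` (logical),
#'   `candidates` (intensities scanned) and `criterion` (J at each
#'   candidate).
#' @export
compute_threshold <- function(image, mask) {
  stopifnot(inherits(image, "grey_image"), inherits(mask, "breast_mask"))
  if (!identical(dim(mask$pixels), dim(image$pixels)))
    stop("mask dimensions do not match image dimensions")
  vals <- image$pixels[mask$pixels]
  .between_class_threshold(vals)
}

#' Segment dense tissue at a given threshold
#'
#' Dense tissue is every breast pixel with intensity strictly greater than
#' the threshold. The strict inequality is the fixed convention tying the
#' criterion's class definition to the mask, avoiding off-by-one drift.
#'
#' @param image A [grey_image].
#' @param mask A [breast_mask] with the image's dimensions.
#' @param threshold Intensity cut (numeric).
#' @return A [dense_mask], a subset of `mask`.
#' @export
segment_dense <- function(image, mask, threshold) {
  stopifnot(inherits(image, "grey_image"), inherits(mask, "breast_mask"))
  if (!identical(dim(mask$pixels), dim(image$pixels)))
    stop("mask dimensions do not match image dimensions")
  dense_mask(mask$pixels & image$pixels > threshold, breast = mask)
}

#' Measure dense area and percent density
#'
#' @param breast A [breast_mask].
#' @param dense A [dense_mask] that is a subset of `breast`.
#' @return List with `breast_area_px`, `dense_area_px` and
#'   `percent_density` (`100 * dense / breast`).
#' @export
measure_density <- function(breast, dense) {
  stopifnot(inherits(breast, "breast_mask"), inherits(dense, "dense_mask"))
  if (breast$area_px == 0L) stop("breast area is zero")
  if (any(dense$pixels & !breast$pixels))
    stop("dense mask is not a subset of the breast mask")
  list(breast_area_px = breast$area_px,
       dense_area_px = dense$area_px,
       percent_density = 100 * dense$area_px / breast$area_px)
}

#' Run the full density measurement pipeline on one mammogram
#'
#' Breast segmentation, median smoothing, contrast stretching, optimal
#' thresholding, dense segmentation and density measurement, in that order.
#' Breast segmentation failures propagate with their reason code; the
#' density stages themselves never fail on a successfully segmented breast.
#'
#' @param image A raw [grey_image].
#' @param config Pipeline configuration from [density_config].
#' @param keep_masks Keep the breast and dense masks on the result (needed
#'   for overlay output; default `FALSE`).
#' @return A `density_result`: list with `source_id`, `status`
#'   (`"success"`/`"failure"`) and, on success, `threshold`,
#'   `breast_area_px`, `dense_area_px`, `percent_density`, `degenerate`,
#'   plus `breast`/`dense` masks when `keep_masks = TRUE`; on failure,
#'   `reason`.
#' @export
process_image <- function(image, config = density_config(),
                          keep_masks = FALSE) {
  stopifnot(inherits(image, "grey_image"))
  seg <- segment_breast(image, config)
  if (!identical(seg$status, "success"))
    return(structure(list(source_id = image$source_id, status = "failure",
                          reason = seg$reason), class = "density_result"))
  smooth <- median_smooth(image, seg$mask, radius = config$median_radius)
  stretched <- contrast_stretch(smooth, seg$mask,
                                lo_pct = config$stretch_lo_pct,
                                hi_pct = config$stretch_hi_pct)
  thr <- compute_threshold(stretched, seg$mask)
  if (thr$degenerate)
    message("degenerate breast histogram for '", image$source_id,
            "': dense area set to 0")
  dense <- segment_dense(stretched, seg$mask, thr$threshold)
  meas <- measure_density(seg$mask, dense)
  res <- list(source_id = image$source_id, status = "success",
              threshold = thr$threshold,
              breast_area_px = meas$breast_area_px,
              dense_area_px = meas$dense_area_px,
              percent_density = meas$percent_density,
              degenerate = thr$degenerate)
  if (keep_masks) {
    res$breast <- seg$mask
    res$dense <- dense
  }
  structure(res, class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  if (identical(x$status, "success")) {
    cat(sprintf(
      "<density_result '%s': breast %d px, dense %d px, PD %.2f%%, t=%g>\n",
      x$source_id, x$breast_area_px, x$dense_area_px, x$percent_density,
      x$threshold))
  } else {
    cat(sprintf("<density_result '%s': %s>\n", x$source_id, x$reason))
  }
  invisible(x)
}
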