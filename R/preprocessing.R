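# Contrast improvement and noise reduction of the breast area before
# dense/fatty thresholding. Both operations act only on breast pixels and
# leave the rest of the image bit-identical, so nothing outside the breast
# can leak into the threshold search.

#' Median-smooth the breast area
#'
#' Replaces each breast pixel by the median of the breast pixels inside its
#' `(2r+1) x (2r+1)` window. The window is restricted to breast pixels: at
#' the breast boundary the background is excluded outright instead of being
#' mirrored or zero-padded, so background zeros cannot drag boundary medians
#' down. Even-sized windows take the lower integer mean of the two central
#' order statistics.
#'
#' @param image A [grey_image].
#' @param mask A [breast_mask] with the image's dimensions.
#' @param radius Window radius in pixels, `>= 1` (default 1).
#' @return A [grey_image] with smoothed breast pixels.
#' @export
median_smooth <- function(image, mask, radius = 1L) {
  stopifnot(inherits(image, "grey_image"), inherits(mask, "breast_mask"))
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be >= 1")
  if (!identical(dim(mask$pixels), dim(image$pixels)))
    stop("mask dimensions do not match image dimensions")
  out <- .masked_median_filter(image$pixels, mask$pixels, radius)
  grey_image(out, image$bit_depth, image$source_id)
}

#' Histogram contrast stretch of the breast area
#'
#' Linearly rescales breast intensities so the `lo_pct` percentile of breast
#' pixels maps to 0 and the `hi_pct` percentile to full scale, with values
#' beyond the clip points saturating. Clipping at the 1st/99th percentiles
#' (the defaults) keeps the stretch robust to residual specks;
#' `lo_pct = 0, hi_pct = 100` recovers a pure min--max stretch. Percentiles
#' are nearest-rank on the sorted breast-pixel multiset. A breast with fewer
#' than two distinct intensities (or coincident clip points) is returned
#' unchanged.
#'
#' @param image A [grey_image].
#' @param mask A [breast_mask] with the image's dimensions.
#' @param lo_pct,hi_pct Clip percentiles in `[0, 100]`, `lo_pct < hi_pct`.
#' @return A [grey_image] with stretched breast pixels; non-breast pixels
#'   bit-identical.
#' @export
contrast_stretch <- function(image, mask, lo_pct = 1, hi_pct = 99) {
  stopifnot(inherits(image, "grey_image"), inherits(mask, "breast_mask"))
  if (!identical(dim(mask$pixels), dim(image$pixels)))
    stop("mask dimensions do not match image dimensions")
  if (lo_pct < 0 || hi_pct > 100 || lo_pct >= hi_pct)
    stop("require 0 <= lo_pct < hi_pct <= 100")
  px <- image$pixels
  vals <- px[mask$pixels]
  lo <- .nearest_rank(vals, lo_pct)
  hi <- .nearest_rank(vals, hi_pct)
  if (lo_pct == 0) lo <- min(vals)       # nearest-rank at 0 is the minimum
  if (lo >= hi) return(image)            # degenerate: (near-)constant breast
  maxv <- .max_intensity(image)
  stretched <- round((as.numeric(vals) - lo) / (hi - lo) * maxv)
  px[mask$pixels] <- as.integer(pmin(pmax(stretched, 0), maxv))
  grey_image(px, image$bit_depth, image$source_id)
}
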