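#' Greyscale mammogram image
#'
#' Container for a single-channel digitised mammogram. Pixels are stored as
#' an integer matrix at the image's native bit depth: no rescaling to 8-bit
#' ever happens internally, because the adaptive threshold search space is
#' the native intensity range and digitiser settings of scanned film are in
#' general unknown.
#'
#' @param pixels Integer matrix of intensities; rows are image rows (y),
#'   columns are image columns (x). Column 1 is the left image edge.
#' @param bit_depth Either 8 or 16. All intensities must lie in
#'   `[0, 2^bit_depth - 1]`.
#' @param source_id Opaque identifier carried through to results tables.
#'
#' @return An object of class `grey_image` with fields `pixels`,
#'   `bit_depth`, `source_id`.
#' @export
grey_image <- function(pixels, bit_depth = 8L, source_id = "image") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  pixels <- matrix(as.integer(round(pixels)), nrow(pixels), ncol(pixels))
  if (anyNA(pixels)) stop("`pixels` contains missing values")
  maxv <- 2L^as.integer(bit_depth) - 1L
  if (min(pixels) < 0L || max(pixels) > maxv)
    stop("intensities outside [0, ", maxv, "] for bit depth ", bit_depth)
  if (ncol(pixels) < 64L || nrow(pixels) < 64L)
    stop("image must be at least 64x64 pixels")
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         source_id = as.character(source_id)),
    class = "grey_image"
  )
}

#' @export
print.grey_image <- function(x, ...) {
  cat(sprintf("<grey_image '%s': %dx%d, %d-bit, range [%d, %d]>\n",
              x$source_id, ncol(x$pixels), nrow(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.grey_image <- function(x) dim(x$pixels)

.max_intensity <- function(image) 2L^image$bit_depth - 1L

#' Binary breast mask
#'
#' The breast area of a mammogram: a single 4-connected component of pixels,
#' attached to exactly one vertical image edge (the chest wall).
#'
#' @param pixels Logical matrix, `TRUE` for breast pixels.
#' @param chest_edge `"left"` or `"right"`: the vertical edge the breast
#'   touches.
#' @param check If `TRUE` (default) enforce the single-component invariant.
#' @return Object of class `breast_mask` with fields `pixels`, `area_px`,
#'   `chest_edge`.
#' @export
breast_mask <- function(pixels, chest_edge = c("left", "right"),
                        check = TRUE) {
  chest_edge <- match.arg(chest_edge)
  stopifnot(is.matrix(pixels), is.logical(pixels))
  area <- sum(pixels)
  if (area == 0L) stop("breast mask is empty")
  if (check) {
    lab <- .label_components4(pixels)
    if (max(lab) != 1L) stop("breast mask must be one 4-connected component")
  }
  structure(list(pixels = pixels, area_px = as.integer(area),
                 chest_edge = chest_edge),
            class = "breast_mask")
}

#' Binary dense-tissue mask
#'
#' Pixels classified as dense tissue; always a subset of the breast mask it
#' was derived from. May consist of several components.
#'
#' @param pixels Logical matrix, `TRUE` for dense pixels.
#' @param breast Optional `breast_mask`; when supplied the subset invariant
#'   is enforced.
#' @return Object of class `dense_mask` with fields `pixels`, `area_px`.
#' @export
dense_mask <- function(pixels, breast = NULL) {
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (!is.null(breast)) {
    if (!identical(dim(pixels), dim(breast$pixels)))
      stop("dense mask and breast mask dimensions differ")
    if (any(pixels & !breast$pixels))
      stop("dense mask must be a subset of the breast mask")
  }
  structure(list(pixels = pixels, area_px = as.integer(sum(pixels))),
            class = "dense_mask")
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask: %d px, chest edge %s>\n", x$area_px,
              x$chest_edge))
  invisible(x)
}

#' @export
print.dense_mask <- function(x, ...) {
  cat(sprintf("<dense_mask: %d px>\n", x$area_px))
  invisible(x)
}

# Which image edges a logical component touches, optionally extending each
# edge inward by a stripped-border width (a component truncated by a scanner
# frame still "touches" that edge).
.edges_touched <- function(pixels, border_widths = c(left = 0L, right = 0L,
                                                     top = 0L, bottom = 0L)) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  bw <- border_widths
  c(left   = any(pixels[, min(nc, bw[["left"]] + 1L)]),
    right  = any(pixels[, max(1L, nc - bw[["right"]])]),
    top    = any(pixels[min(nr, bw[["top"]] + 1L), ]),
    bottom = any(pixels[max(1L, nr - bw[["bottom"]]), ]))
}
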