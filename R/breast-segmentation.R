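# Breast-area segmentation: scanner-border stripping, detached-artefact
# detection, and largest-component breast selection with characterised
# failure modes. Digitised film mammograms carry bright borders from the
# scanning process plus detached high-intensity blobs (laterality/view tags,
# nameplates) that must not be mistaken for tissue.

# Detect a bright scanner frame. For each image side, edge-adjacent
# rows/columns whose mean intensity reaches the `border_percentile`-th
# percentile of the whole image are grown inward while the criterion holds,
# capped at `max_border_frac` of the dimension. Returns per-side widths and
# the border pixel mask. Constant (or near-constant) images have no
# detectable border: the percentile then equals the median and detection is
# skipped.
.detect_border <- function(px, config = density_config()) {
  nr <- nrow(px); nc <- ncol(px)
  widths <- c(left = 0L, right = 0L, top = 0L, bottom = 0L)
  thr <- .nearest_rank(as.vector(px), config$border_percentile)
  if (thr <= median(px))
    return(list(widths = widths, mask = matrix(FALSE, nr, nc)))
  cap_c <- floor(config$max_border_frac * nc)
  cap_r <- floor(config$max_border_frac * nr)
  grow <- function(idx_means, cap) {
    w <- 0L
    while (w < cap && idx_means(w + 1L) >= thr) w <- w + 1L
    w
  }
  widths[["left"]]   <- grow(function(k) mean(px[, k]), cap_c)
  widths[["right"]]  <- grow(function(k) mean(px[, nc - k + 1L]), cap_c)
  widths[["top"]]    <- grow(function(k) mean(px[k, ]), cap_r)
  widths[["bottom"]] <- grow(function(k) mean(px[nr - k + 1L, ]), cap_r)
  mask <- matrix(FALSE, nr, nc)
  if (widths[["left"]] > 0L)   mask[, seq_len(widths[["left"]])] <- TRUE
  if (widths[["right"]] > 0L)  mask[, nc - seq_len(widths[["right"]]) + 1L] <- TRUE
  if (widths[["top"]] > 0L)    mask[seq_len(widths[["top"]]), ] <- TRUE
  if (widths[["bottom"]] > 0L) mask[nr - seq_len(widths[["bottom"]]) + 1L, ] <- TRUE
  list(widths = widths, mask = mask)
}

#' Strip bright scanner borders from a mammogram
#'
#' Zeroes pixels belonging to a bright frame running along the image edges
#' (a scanning artefact of digitised film); interior pixels are unchanged.
#' A no-op when no border is detected.
#'
#' @param image A [grey_image].
#' @param config Pipeline configuration from [density_config].
#' @return A [grey_image] with border pixels set to 0.
#' @export
strip_border <- function(image, config = density_config()) {
  stopifnot(inherits(image, "grey_image"))
  bd <- .detect_border(image$pixels, config)
  px <- image$pixels
  px[bd$mask] <- 0L
  grey_image(px, image$bit_depth, image$source_id)
}

# Foreground decomposition shared by artefact detection and breast
# selection: background/tissue split by the between-class-variance threshold
# on the border-stripped histogram, then 4-connected labelling. The breast
# candidate is the largest foreground component; ties prefer a component
# touching a vertical image edge, then the lowest label.
.foreground_components <- function(px, border, config) {
  vals <- px[!border]
  ot <- .between_class_threshold(vals)
  if (ot$degenerate) return(NULL)
  fg <- (px > ot$threshold) & !border
  if (!any(fg)) return(NULL)
  lab <- .label_components4(fg)
  sizes <- tabulate(lab[lab > 0L])
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    nc <- ncol(px)
    touches_v <- vapply(cand, function(l) {
      m <- lab == l
      any(m[, 1L]) || any(m[, nc])
    }, logical(1))
    if (any(touches_v)) cand <- cand[touches_v]
    cand <- min(cand)
  }
  list(labels = lab, sizes = sizes, candidate = cand,
       threshold = ot$threshold)
}

#' Detect detached bright artefacts
#'
#' Finds bright connected components that are not part of the breast
#' component: laterality/view tags, nameplates and similar detached blobs.
#' An artefact that overlaps the breast merges with it under 4-connectivity
#' and is by definition not detached, so it is not returned here (such
#' images surface as segmentation failures downstream).
#'
#' @param image A [grey_image] with scanner borders already stripped
#'   (see [strip_border]).
#' @param config Pipeline configuration from [density_config].
#' @return Logical matrix marking artefact pixels (all `FALSE` when none).
#' @export
detect_artifacts <- function(image, config = density_config()) {
  stopifnot(inherits(image, "grey_image"))
  px <- image$pixels
  fc <- .foreground_components(px, matrix(FALSE, nrow(px), ncol(px)), config)
  if (is.null(fc)) return(matrix(FALSE, nrow(px), ncol(px)))
  fc$labels > 0L & fc$labels != fc$candidate
}

#' Segment the breast area of a mammogram
#'
#' Full breast segmentation: strips scanner borders, separates background
#' from tissue with a between-class-variance threshold on the
#' border-stripped histogram, and selects the largest non-artefact
#' foreground component as the breast. Failure is declared -- rather than
#' guessed around -- when the candidate breast touches both vertical image
#' edges, touches three or more edges, touches no vertical edge at all, or
#' occupies more than `max_breast_frac` or less than `min_breast_frac` of
#' the image. A component truncated by a stripped border band counts as
#' touching the edge behind that band.
#'
#' @param image A [grey_image] (raw; borders are stripped internally).
#' @param config Pipeline configuration from [density_config].
#' @return A `segmentation_outcome`: list with `status`
#'   (`"success"`/`"failure"`) and, on success, `mask` (a [breast_mask]),
#'   `artifacts` (logical matrix), `background_threshold` and
#'   `border_widths`; on failure, `reason`
#'   (`"FAIL_BREAST_SEGMENTATION"` or `"FAIL_EMPTY_IMAGE"`).
#' @export
segment_breast <- function(image, config = density_config()) {
  stopifnot(inherits(image, "grey_image"))
  px <- image$pixels
  fail <- function(reason)
    structure(list(status = "failure", reason = reason),
              class = "segmentation_outcome")
  if (min(px) == max(px)) return(fail("FAIL_EMPTY_IMAGE"))
  bd <- .detect_border(px, config)
  px[bd$mask] <- 0L
  if (min(px) == max(px)) return(fail("FAIL_EMPTY_IMAGE"))
  fc <- .foreground_components(px, bd$mask, config)
  if (is.null(fc)) return(fail("FAIL_EMPTY_IMAGE"))
  cand_px <- fc$labels == fc$candidate
  area <- sum(cand_px)
  npx <- length(px)
  edges <- .edges_touched(cand_px, bd$widths)
  n_vertical <- sum(edges[c("left", "right")])
  if (n_vertical == 2L || sum(edges) >= 3L || n_vertical == 0L ||
      area > config$max_breast_frac * npx || area < config$min_breast_frac * npx)
    return(fail("FAIL_BREAST_SEGMENTATION"))
  # chest wall = the vertical edge with the longer run of breast pixels
  # (laterality tags are artefacts and deliberately play no part here)
  bw <- bd$widths
  nc <- ncol(cand_px)
  run_left  <- sum(cand_px[, min(nc, bw[["left"]] + 1L)])
  run_right <- sum(cand_px[, max(1L, nc - bw[["right"]])])
  chest <- if (run_left >= run_right) "left" else "right"
  structure(list(
    status = "success",
    mask = breast_mask(cand_px, chest_edge = chest, check = FALSE),
    artifacts = fc$labels > 0L & fc$labels != fc$candidate,
    background_threshold = fc$threshold,
    border_widths = bd$widths
  ), class = "segmentation_outcome")
}

#' @export
print.segmentation_outcome <- function(x, ...) {
  if (identical(x$status, "success")) {
    cat(sprintf("<segmentation: success, %d px, chest edge %s>\n",
                x$mask$area_px, x$mask$chest_edge))
  } else {
    cat(sprintf("<segmentation: failure (%s)>\n", x$reason))
  }
  invisible(x)
}
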