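# Synthetic digitised-film-style mammogram phantoms with ground-truth
# masks. A phantom is a half-ellipse "breast" attached to one vertical image
# edge, containing dense discs of controllable area fraction and contrast,
# plus the background artefacts characteristic of scanned film: a bright
# border frame and a detached high-intensity tag blob. Noise is additive
# Gaussian film grain, clipped to the intensity range.

#' Specify a synthetic mammogram phantom
#'
#' @param width,height Image size in pixels (>= 64 each).
#' @param bit_depth 8 or 16.
#' @param breast_semi_x,breast_semi_y Semi-axes of the half-ellipse breast,
#'   as fractions of width and height. The ellipse is centred on the
#'   attached edge at mid-height; `breast_semi_x >= 1` makes the breast span
#'   the full width (touching both vertical edges), which is how
#'   deliberately invalid phantoms for failure-mode tests are built.
#' @param attached_edge `"left"` or `"right"`: the chest-wall edge.
#' @param dense_fraction Target dense fraction of the breast area in
#'   `[0, 1]`; the realised fraction is solved to within `fraction_tol`.
#' @param n_discs Number of dense discs composing the dense region.
#' @param fatty_mean,dense_mean,background_mean Mean intensities of fatty
#'   tissue, dense tissue and background (native intensity units;
#'   `dense_mean > fatty_mean` required when `dense_fraction > 0`).
#' @param noise_sd Gaussian film-grain standard deviation (intensity units).
#' @param border_width Bright scanner frame width in pixels (0 = none).
#' @param border_intensity Frame intensity; defaults to the maximum.
#' @param tag Add a detached bright tag blob in the background?
#' @param tag_size Tag side length in pixels.
#' @param fraction_tol Tolerance on the realised dense fraction (default
#'   0.02 of breast area).
#' @param seed RNG seed (required; generation is deterministic given the
#'   spec).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 256L, height = 256L, bit_depth = 8L,
                         breast_semi_x = 0.62, breast_semi_y = 0.40,
                         attached_edge = c("left", "right"),
                         dense_fraction = 0.25, n_discs = 8L,
                         fatty_mean = 110, dense_mean = 190,
                         background_mean = 8, noise_sd = 6,
                         border_width = 0L,
                         border_intensity = NULL,
                         tag = FALSE, tag_size = 20L,
                         fraction_tol = 0.02, seed) {
  attached_edge <- match.arg(attached_edge)
  if (missing(seed)) stop("`seed` is required")
  if (dense_fraction < 0 || dense_fraction > 1)
    stop("`dense_fraction` must be in [0, 1]")
  if (dense_fraction > 0 && dense_mean <= fatty_mean)
    stop("`dense_mean` must exceed `fatty_mean` for a contrast phantom")
  maxv <- 2^as.integer(bit_depth) - 1
  if (is.null(border_intensity)) border_intensity <- maxv
  if (fatty_mean > maxv || dense_mean > maxv || background_mean > maxv)
    stop("mean intensities exceed the bit-depth range")
  structure(list(
    width = as.integer(width), height = as.integer(height),
    bit_depth = as.integer(bit_depth),
    breast_semi_x = breast_semi_x, breast_semi_y = breast_semi_y,
    attached_edge = attached_edge,
    dense_fraction = dense_fraction, n_discs = as.integer(n_discs),
    fatty_mean = fatty_mean, dense_mean = dense_mean,
    background_mean = background_mean, noise_sd = noise_sd,
    border_width = as.integer(border_width),
    border_intensity = border_intensity,
    tag = isTRUE(tag), tag_size = as.integer(tag_size),
    fraction_tol = fraction_tol, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards: one seeded RNG per generation call, no
# hidden global state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Union of discs clipped to the breast, with radii scaled by `s`; returns
# the logical dense mask. `cx`, `cy`, `r` are disc centres/base radii.
.disc_union <- function(xg, yg, breast, cx, cy, r, s) {
  dense <- matrix(FALSE, nrow(breast), ncol(breast))
  for (k in seq_along(cx)) {
    rk <- s * r[k]
    dense <- dense | ((xg - cx[k])^2 + (yg - cy[k])^2 <= rk^2)
  }
  dense & breast
}

#' Generate a synthetic mammogram phantom with ground truth
#'
#' Deterministic for a given spec (same spec + seed gives bit-identical
#' output). Dense geometry is a union of randomly centred discs whose
#' common radius scale is solved by bisection until the realised dense
#' fraction is within `fraction_tol` of the target; after 100 re-seeded
#' attempts a generation error is raised rather than silently missing the
#' target.
#'
#' @param spec A [phantom_spec].
#' @return List with `image` (a [grey_image]), `breast` (ground-truth
#'   [breast_mask]), `dense` (ground-truth [dense_mask]),
#'   `realised_fraction`, `artifact_mask` (logical: tag pixels),
#'   `border_mask` (logical: frame pixels) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  .with_seed(spec$seed, .generate_phantom_impl(spec))
}

.generate_phantom_impl <- function(spec) {
  w <- spec$width; h <- spec$height
  maxv <- 2^spec$bit_depth - 1
  xg <- matrix(rep(seq_len(w), each = h), h, w)   # column (x) index
  yg <- matrix(rep(seq_len(h), times = w), h, w)  # row (y) index
  a <- spec$breast_semi_x * w
  b <- spec$breast_semi_y * h
  cy <- (h + 1) / 2
  x0 <- if (spec$attached_edge == "left") 1 else w
  breast <- ((xg - x0) / a)^2 + ((yg - cy) / b)^2 <= 1
  if (!any(breast)) stop("phantom generation error: empty breast region")

  # dense geometry: discs centred on breast pixels, radius scale solved by
  # bisection on the realised fraction (monotone in the scale)
  dense <- matrix(FALSE, h, w)
  target <- spec$dense_fraction
  if (target > 0) {
    barea <- sum(breast)
    r0 <- sqrt(barea / pi)
    idx <- which(breast)
    solved <- FALSE
    for (attempt in seq_len(100L)) {
      ctr <- sample(idx, spec$n_discs, replace = TRUE)
      dcx <- xg[ctr]; dcy <- yg[ctr]
      r <- runif(spec$n_discs, 0.15, 0.45) * r0
      frac_at <- function(s)
        sum(.disc_union(xg, yg, breast, dcx, dcy, r, s)) / barea
      lo <- 0; hi <- 1
      while (frac_at(hi) < target && hi < 64) hi <- hi * 2
      for (it in seq_len(50L)) {
        mid <- (lo + hi) / 2
        if (frac_at(mid) < target) lo <- mid else hi <- mid
      }
      s <- hi
      dense <- .disc_union(xg, yg, breast, dcx, dcy, r, s)
      if (abs(sum(dense) / barea - target) <= spec$fraction_tol) {
        solved <- TRUE
        break
      }
    }
    if (!solved)
      stop("phantom generation error: could not realise dense fraction ",
           target, " within ", spec$fraction_tol)
  }

  img <- matrix(spec$background_mean, h, w)
  img[breast] <- spec$fatty_mean
  img[dense] <- spec$dense_mean

  # detached tag blob in the background, opposite the chest wall
  artifact <- matrix(FALSE, h, w)
  if (spec$tag) {
    ts <- spec$tag_size
    margin <- spec$border_width + 6L
    rows <- margin + seq_len(ts)
    cols <- if (spec$attached_edge == "left")
      w - margin - ts + seq_len(ts) else margin + seq_len(ts)
    if (any(breast[rows, cols]))
      stop("phantom generation error: tag would overlap the breast")
    artifact[rows, cols] <- TRUE
    img[artifact] <- 0.9 * maxv
  }

  if (spec$noise_sd > 0)
    img <- img + rnorm(length(img), 0, spec$noise_sd)

  border <- matrix(FALSE, h, w)
  if (spec$border_width > 0L) {
    bwd <- spec$border_width
    border[c(seq_len(bwd), h - seq_len(bwd) + 1L), ] <- TRUE
    border[, c(seq_len(bwd), w - seq_len(bwd) + 1L)] <- TRUE
    img[border] <- spec$border_intensity
  }

  img <- matrix(as.integer(round(pmin(pmax(img, 0), maxv))), h, w)
  gi <- grey_image(img, spec$bit_depth,
                   source_id = sprintf("phantom_%d", spec$seed))
  bm <- structure(list(pixels = breast, area_px = as.integer(sum(breast)),
                       chest_edge = spec$attached_edge),
                  class = "breast_mask")
  list(image = gi, breast = bm, dense = dense_mask(dense),
       realised_fraction = if (spec$dense_fraction > 0)
         sum(dense) / sum(breast) else 0,
       artifact_mask = artifact, border_mask = border, spec = spec)
}
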