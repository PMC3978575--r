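#' Pipeline configuration
#'
#' Returns the full configuration list used by the measurement pipeline,
#' with any supplied values overriding the defaults. All tunables are
#' collected here so a run can be reproduced from its config snapshot.
#'
#' @param ... Named overrides of the defaults below.
#' @return Named list with elements:
#' \describe{
#'   \item{border_percentile}{Whole-image intensity percentile an
#'     edge-adjacent row/column mean must reach to count as scanner border
#'     (default 99).}
#'   \item{max_border_frac}{Cap on detected border width as a fraction of
#'     the image dimension (default 0.10).}
#'   \item{min_breast_frac, max_breast_frac}{Acceptable breast area as a
#'     fraction of image area (defaults 0.01 and 0.90); outside this range
#'     the segmentation is declared failed.}
#'   \item{connectivity}{Pixel connectivity; fixed at 4.}
#'   \item{median_radius}{Median filter radius in pixels (default 1).}
#'   \item{stretch_lo_pct, stretch_hi_pct}{Clip percentiles for the
#'     contrast stretch (defaults 1 and 99; 0/100 recovers a pure
#'     min--max stretch).}
#'   \item{criterion}{Dense/fatty threshold criterion; currently
#'     `"between_class_variance"`.}
#' }
#' @export
density_config <- function(...) {
  cfg <- list(
    border_percentile = 99,
    max_border_frac = 0.10,
    min_breast_frac = 0.01,
    max_breast_frac = 0.90,
    connectivity = 4L,
    median_radius = 1L,
    stretch_lo_pct = 1,
    stretch_hi_pct = 99,
    criterion = "between_class_variance"
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (!identical(as.integer(cfg$connectivity), 4L))
    stop("only 4-connectivity is supported")
  cfg
}

# Between-class threshold criterion on a histogram of integer intensities.
#
# For a cut t the lower class holds values <= t (counts n0, sum S0) and the
# upper class values > t (n1, S1). The criterion is
#     J(t) = (S0*n1 - S1*n0)^2 / (n0*n1),
# algebraically n0*n1*(mu0 - mu1)^2, a positive rescaling of the classic
# between-class variance, so its maximiser is the between-class-variance
# maximiser. S0, S1, n0, n1 are exact integers (representable in doubles),
# so J is deterministic up to one final rounding and ties are broken by the
# smallest candidate t.
#
# Returns list(threshold, degenerate, candidates, criterion).
.between_class_threshold <- function(vals) {
  u <- sort(unique(as.numeric(vals)))
  if (length(u) == 1L)
    return(list(threshold = u, degenerate = TRUE,
                candidates = u, criterion = 0))
  cnt <- tabulate(match(vals, u), nbins = length(u))
  n <- length(vals)
  cum_n <- cumsum(as.numeric(cnt))
  cum_s <- cumsum(as.numeric(cnt) * u)
  k <- length(u) - 1L                    # t = max(u) leaves the upper class empty
  n0 <- cum_n[seq_len(k)]
  s0 <- cum_s[seq_len(k)]
  n1 <- n - n0
  s1 <- cum_s[length(u)] - s0
  d <- s0 * n1 - s1 * n0
  J <- d * d / (n0 * n1)
  best <- which.max(J)                   # first maximum = smallest t
  list(threshold = u[best], degenerate = FALSE,
       candidates = u[seq_len(k)], criterion = J)
}

# Nearest-rank percentile of an integer sample: the ceil(n*p/100)-th order
# statistic (at least the first).
.nearest_rank <- function(vals, p) {
  s <- sort(vals)
  idx <- max(1L, ceiling(length(s) * p / 100))
  s[min(idx, length(s))]
}
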