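# Independent oracles used across the suite. These are deliberately naive
# (full recomputation per candidate / per pixel / per pair) so they share no
# code path with the package implementation.

# Exhaustive scan of the between-class criterion
# J(t) = (S0*n1 - S1*n0)^2 / (n0*n1) over the candidate thresholds,
# recomputing the class sums from scratch for every candidate. Ties take the
# smallest t, as documented.
oracle_threshold <- function(vals, candidates = NULL) {
  vals <- as.numeric(vals)
  u <- sort(unique(vals))
  if (length(u) == 1L) return(u)
  if (is.null(candidates)) candidates <- u[-length(u)]
  n <- length(vals)
  best_t <- NA_real_
  best_J <- -Inf
  for (t in candidates) {
    lower <- vals <= t
    n0 <- sum(lower)
    n1 <- n - n0
    if (n0 == 0L || n1 == 0L) next
    s0 <- sum(vals[lower])
    s1 <- sum(vals[!lower])
    d <- s0 * n1 - s1 * n0
    J <- d * d / (n0 * n1)
    if (J > best_J) {
      best_J <- J
      best_t <- t
    }
  }
  best_t
}

# Per-pixel mask-restricted median by explicit double loop; even windows
# take the lower integer mean of the two central order statistics.
oracle_masked_median <- function(px, mask, radius) {
  nr <- nrow(px); nc <- ncol(px)
  out <- px
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!mask[i, j]) next
      ii <- max(1, i - radius):min(nr, i + radius)
      jj <- max(1, j - radius):min(nc, j + radius)
      w <- px[ii, jj][mask[ii, jj]]
      w <- sort(w)
      m <- length(w)
      out[i, j] <- if (m %% 2 == 1) w[(m + 1) / 2]
                   else (w[m / 2] + w[m / 2 + 1]) %/% 2
    }
  }
  storage.mode(out) <- "integer"
  out
}

# AUC by exhaustive pair counting, ties worth one half.
oracle_auc <- function(cases, controls) {
  tot <- 0
  for (x in cases)
    for (y in controls)
      tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(cases) * length(controls))
}

# Dice coefficient between two logical masks.
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
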