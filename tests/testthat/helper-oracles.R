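# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's own code paths: explicit loops,
# pair counting and enumeration instead of vectorized formulas.

const_volume <- function(value, dim = c(8, 8, 4), spacing = c(1, 1, 1),
                         phase = "pancreatic") {
  ct_volume(array(value, dim = dim), spacing = spacing, phase = phase)
}

full_mask <- function(vol) {
  ct_mask(array(TRUE, dim = dim(vol$voxels)), spacing = vol$spacing,
          origin = vol$origin)
}

# direct-summation first-order moments (explicit accumulation loop)
oracle_moments <- function(x) {
  n <- length(x)
  s <- 0
  for (v in x) s <- s + v
  mu <- s / n
  m2 <- m3 <- m4 <- 0
  for (v in x) {
    d <- v - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  list(mean = mu, variance = m2,
       skewness = if (m2 > 0) m3 / m2^1.5 else 0,
       kurtosis = if (m2 > 0) m4 / m2^2 - 3 else 0)
}

# entropy recomputed from an explicitly tabulated histogram
oracle_entropy <- function(x, n_bins) {
  if (min(x) == max(x)) return(0)
  breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (v in x) {
    b <- n_bins
    for (j in seq_len(n_bins)) {
      if (v <= breaks[j + 1]) { b <- j; break }
    }
    counts[b] <- counts[b] + 1
  }
  p <- counts[counts > 0] / length(x)
  -sum(p * log2(p))
}

# exhaustive voxel-membership ROI mean
oracle_roi_mean <- function(vol, roi) {
  d <- dim(vol$voxels)
  sl <- vol$voxels[, , roi$slice_index]
  tot <- 0; n <- 0
  for (i in seq_len(d[1])) {      # x / col
    for (j in seq_len(d[2])) {    # y / row
      dx <- (i - roi$center[2]) * vol$spacing[1]
      dy <- (j - roi$center[1]) * vol$spacing[2]
      if (dx^2 + dy^2 <= roi$radius^2) {
        tot <- tot + sl[i, j]; n <- n + 1
      }
    }
  }
  tot / n
}

# pair-counting U and exact two-sided permutation p by full enumeration
oracle_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  mu <- na * length(b) / 2
  u_obs <- oracle_U(a, b)
  cmb <- utils::combn(length(pooled), na)
  hits <- 0
  for (j in seq_len(ncol(cmb))) {
    aa <- pooled[cmb[, j]]
    bb <- pooled[-cmb[, j]]
    if (abs(oracle_U(aa, bb) - mu) >= abs(u_obs - mu) - 1e-9) hits <- hits + 1
  }
  hits / ncol(cmb)
}

# AUC by pair counting with ties counted 1/2
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (x in sp) for (y in sn) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(sp) * length(sn))
}
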