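# First-order (histogram) texture features of the segmented 3D tumor.
#
# Conventions, fixed because texture tools disagree silently:
#   * population (1/N) central moments, not sample-corrected;
#   * kurtosis is EXCESS kurtosis (Gaussian = 0, platykurtic < 0);
#   * entropy is Shannon entropy in bits over an explicit histogram config;
#   * zero-variance samples yield skewness = kurtosis = 0 with a degeneracy
#     flag rather than NaN, so cohort tables stay total.

#' Histogram configuration for entropy
#'
#' @param n_bins Number of equal-width bins (default 128, >= 2).
#' @param range_mode How the histogram support is chosen: `"mask_min_max"`
#'   (sample min..max, the default), `"fixed_window"` (explicit HU window), or
#'   `"mu_pm_3sigma"` (mean +/- 3 SD, the normalization several texture tools
#'   apply before binning).
#' @param window Length-2 `(lo, hi)` HU window, required when
#'   `range_mode = "fixed_window"`.
#' @return An object of class `binning_config`.
#' @export
binning_config <- function(n_bins = 128L,
                           range_mode = c("mask_min_max", "fixed_window",
                                          "mu_pm_3sigma"),
                           window = NULL) {
  range_mode <- match.arg(range_mode)
  n_bins <- as.integer(n_bins)
  if (!is.finite(n_bins) || n_bins < 2L) stop("`n_bins` must be >= 2")
  if (range_mode == "fixed_window") {
    if (is.null(window) || length(window) != 2L || !all(is.finite(window)) ||
        window[1] >= window[2])
      stop("`fixed_window` mode needs window = c(lo, hi) with lo < hi")
    window <- as.numeric(window)
  } else {
    window <- NULL
  }
  structure(list(n_bins = n_bins, range_mode = range_mode, window = window,
                 log_base = 2),
            class = "binning_config")
}

#' Extract the masked intensity sample
#'
#' Returns the HU values of every mask-interior voxel of a volume, in array
#' (column-major) order. Volume and mask must live on the identical grid; a
#' mismatch is an error, never an implicit resample.
#'
#' @param vol A [ct_volume()].
#' @param mask A [ct_mask()] on the same grid.
#' @return Numeric vector of length `sum(mask$voxels)`.
#' @export
extract_voxels <- function(vol, mask) {
  stopifnot(inherits(vol, "ct_volume"), inherits(mask, "ct_mask"))
  if (!same_geometry(vol, mask)) stop_geometry_mismatch("volume and mask")
  vol$voxels[mask$voxels]
}

histogram_probs <- function(x, cfg) {
  rng <- switch(cfg$range_mode,
    mask_min_max = range(x),
    fixed_window = cfg$window,
    mu_pm_3sigma = {
      mu <- mean(x); s <- stats::sd(x)
      c(mu - 3 * s, mu + 3 * s)
    })
  if (!all(is.finite(rng)) || rng[1] >= rng[2]) {
    # constant sample (or zero-variance window): all mass in one bin
    return(1)
  }
  breaks <- seq(rng[1], rng[2], length.out = cfg$n_bins + 1L)
  xx <- x[x >= rng[1] & x <= rng[2]]  # fixed/3-sigma windows may clip
  if (length(xx) == 0L) return(1)
  b <- findInterval(xx, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(b, nbins = cfg$n_bins)
  counts / sum(counts)
}

#' First-order features of an intensity sample
#'
#' With `N` values `x_i`, `mu = sum(x_i)/N` and population central moments
#' `m_k = sum((x_i - mu)^k)/N`:
#' mean = `mu`, variance = `m_2`, skewness = `m_3 / m_2^1.5`,
#' kurtosis = `m_4 / m_2^2 - 3` (excess), and entropy
#' `-sum(p_b log2 p_b)` over the configured histogram (empty bins contribute
#' nothing). A constant sample is degenerate: skewness, kurtosis and entropy
#' are 0 and `degenerate_flag` is set.
#'
#' @param sample Numeric vector of voxel intensities (HU), length >= 1.
#' @param cfg A [binning_config()] (entropy only).
#' @param intensity_offset Constant added to the sample before analysis
#'   (default 0). Lets users emulate tools that operate on raw stored gray
#'   levels (e.g. HU + 1024) instead of HU; mean shifts by the offset, all
#'   other features are offset-invariant under `mask_min_max` binning.
#' @return An object of class `texture_panel`: list with `mean_value`,
#'   `variance`, `skewness`, `kurtosis`, `entropy`, `n_voxels`, `n_bins`,
#'   `degenerate_flag`.
#' @export
first_order_features <- function(sample, cfg = binning_config(),
                                 intensity_offset = 0) {
  if (length(sample) < 1L) stop("empty intensity sample")
  if (any(!is.finite(sample))) stop("non-finite values in intensity sample")
  stopifnot(inherits(cfg, "binning_config"))
  x <- as.numeric(sample) + intensity_offset
  n <- length(x)
  mu <- mean(x)
  d <- x - mu
  m2 <- mean(d^2)
  degenerate <- (m2 == 0)
  if (degenerate) {
    skew <- 0; kurt <- 0; ent <- 0
  } else {
    m3 <- mean(d^3)
    m4 <- mean(d^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
    p <- histogram_probs(x, cfg)
    p <- p[p > 0]
    ent <- -sum(p * log2(p))
  }
  structure(
    list(mean_value = mu, variance = m2, skewness = skew, kurtosis = kurt,
         entropy = ent, n_voxels = n, n_bins = cfg$n_bins,
         degenerate_flag = degenerate),
    class = "texture_panel"
  )
}

#' @export
print.texture_panel <- function(x, ...) {
  cat(sprintf(
    paste0("<texture_panel> n=%d voxels | mean %.2f  var %.2f  skew %.3f  ",
           "ex.kurt %.3f  entropy %.3f bits (%d bins)%s\n"),
    x$n_voxels, x$mean_value, x$variance, x$skewness, x$kurtosis, x$entropy,
    x$n_bins, if (x$degenerate_flag) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Texture panel of a segmented study
#'
#' Composition of [extract_voxels()] and [first_order_features()]. Texture is
#' analyzed on the pancreatic (arterial) phase — the phase that best depicts
#' the tumor's arterial network — so any other phase label is rejected unless
#' `allow_any_phase = TRUE`.
#'
#' @param vol The pancreatic-phase [ct_volume()], already standardized to the
#'   analysis slice thickness (see [resample_slices()]).
#' @param mask The tumor [ct_mask()] on the same grid.
#' @param cfg A [binning_config()].
#' @param allow_any_phase Set `TRUE` to analyze a non-pancreatic phase.
#' @inheritParams first_order_features
#' @return A `texture_panel`.
#' @export
texture_from_study <- function(vol, mask, cfg = binning_config(),
                               allow_any_phase = FALSE, intensity_offset = 0) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!allow_any_phase && vol$phase != "pancreatic")
    stop("texture is defined on the pancreatic (arterial) phase; got '",
         vol$phase, "' (use allow_any_phase = TRUE to override)")
  first_order_features(extract_voxels(vol, mask), cfg,
                       intensity_offset = intensity_offset)
}
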