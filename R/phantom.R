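# Synthetic multiphase CT phantom cohort.
#
# Each phantom patient is an ellipsoidal lesion embedded in uniform pancreatic
# parenchyma with an aorta and a portal vein, imaged on three contrast phases.
# Tumor voxels follow a two-component Gaussian mixture: viable tissue plus
# spatially clustered hypodense (necrotic/fibrotic) blobs occupying a
# grade-dependent volume fraction. The marginal intensity distribution of the
# mask is therefore an analytically tractable mixture, which is recorded as
# ground truth: heterogeneous grades become leptokurtic exactly the way a
# small admixture of strongly hypodense tissue fattens a histogram's tails.

#' Grade-specific phantom profile
#'
#' Collects the generative parameters for one tumor grade. Enhancement means
#' follow the per-grade pancreatic/portal tumor attenuations reported for
#' panNEN cohorts (G1 hyperenhancing, G3 hypoenhancing); vessel and pancreas
#' values are calibration constants chosen so the resulting ratio panels fall
#' inside the published per-grade envelopes. Heterogeneity is controlled by
#' `necrosis_fraction` (volume fraction of hypodense tissue) and
#' `necrosis_hu_delta` (its attenuation offset, negative).
#'
#' @param grade `"G1"`, `"G2"` or `"G3"`.
#' @param tumor_hu_art,tumor_hu_port Length-2 `(mean, sd)` of the per-patient
#'   viable-tissue mean HU on the pancreatic / portal phase. The sd is the
#'   between-patient spread.
#' @param pancreas_hu_art,pancreas_hu_port,aorta_hu,portal_vein_hu Background
#'   and vessel mean HU (scalars).
#' @param necrosis_fraction Target volume fraction of necrotic tissue, in
#'   `[0, 1)`.
#' @param necrosis_hu_delta Mean HU offset of necrotic voxels (negative).
#' @param necrosis_sd,viable_sd Within-component voxel noise SD in HU (> 0).
#' @param irregular_margin_prob Probability of irregular lesion margins.
#' @param lesion_radius_mm Length-2 `(mean, sd)` of the in-plane lesion
#'   radius in mm.
#' @param qualitative_probs Named list of Bernoulli probabilities for the
#'   sampled qualitative flags: `hypodense_areas`, `calcifications`,
#'   `mpd_dilation`, `cbd_dilation`, `vessel_involvement`, `liver_metastases`,
#'   `heterogeneous_enhancement`.
#' @return An object of class `grade_profile`.
#' @export
grade_profile <- function(grade, tumor_hu_art, tumor_hu_port,
                          pancreas_hu_art = 110, pancreas_hu_port = 100,
                          aorta_hu = 300, portal_vein_hu = 150,
                          necrosis_fraction = 0, necrosis_hu_delta = -30,
                          necrosis_sd = 12, viable_sd = 12,
                          irregular_margin_prob = 0.1,
                          lesion_radius_mm = c(22, 4),
                          qualitative_probs = list()) {
  grade <- match.arg(grade, c("G1", "G2", "G3"))
  chk2 <- function(x, nm) {
    if (length(x) != 2L || !all(is.finite(x)) || x[2] <= 0)
      stop("`", nm, "` must be (mean, sd) with sd > 0")
    as.numeric(x)
  }
  tumor_hu_art <- chk2(tumor_hu_art, "tumor_hu_art")
  tumor_hu_port <- chk2(tumor_hu_port, "tumor_hu_port")
  lesion_radius_mm <- chk2(lesion_radius_mm, "lesion_radius_mm")
  if (necrosis_fraction < 0 || necrosis_fraction >= 1)
    stop("`necrosis_fraction` must lie in [0, 1)")
  if (necrosis_hu_delta >= 0)
    stop("`necrosis_hu_delta` must be negative (hypodense)")
  if (necrosis_sd <= 0 || viable_sd <= 0) stop("component SDs must be > 0")
  if (irregular_margin_prob < 0 || irregular_margin_prob > 1)
    stop("`irregular_margin_prob` must lie in [0, 1]")
  qp_default <- list(hypodense_areas = 0.3, calcifications = 0.15,
                     mpd_dilation = 0.2, cbd_dilation = 0.12,
                     vessel_involvement = 0.1, liver_metastases = 0.08,
                     heterogeneous_enhancement = 0.5)
  qp <- utils::modifyList(qp_default, qualitative_probs)
  if (any(unlist(qp) < 0 | unlist(qp) > 1))
    stop("qualitative probabilities must lie in [0, 1]")
  structure(
    list(grade = grade, tumor_hu_art = tumor_hu_art,
         tumor_hu_port = tumor_hu_port,
         pancreas_hu_art = pancreas_hu_art,
         pancreas_hu_port = pancreas_hu_port,
         aorta_hu = aorta_hu, portal_vein_hu = portal_vein_hu,
         necrosis_fraction = necrosis_fraction,
         necrosis_hu_delta = necrosis_hu_delta,
         necrosis_sd = necrosis_sd, viable_sd = viable_sd,
         irregular_margin_prob = irregular_margin_prob,
         lesion_radius_mm = lesion_radius_mm,
         qualitative_probs = qp),
    class = "grade_profile"
  )
}

#' Default grade profiles
#'
#' Enhancement means are the reported per-grade tumor attenuations
#' (pancreatic/portal phase: G1 121.90/103.83, G2 107.86/98.84, G3
#' 79.94/89.4 HU). Heterogeneity parameters are calibrated so the analytic
#' excess kurtosis of the tumor mixture reproduces the reported per-grade
#' ordering (G1 approximately 0.04, G2 0.42, G3 2.5 — homogeneous and
#' platykurtic-to-Gaussian at G1, strongly leptokurtic at G3). Note that
#' kurtosis is NOT monotone in the necrotic fraction: a large hypodense
#' fraction yields a bimodal, platykurtic histogram, so G3 combines a modest
#' fraction (0.12) with a deep offset (-70 HU). Margin probabilities follow
#' the published qualitative frequencies (irregular margins 1/31, 16/52,
#' 9/17).
#'
#' @return Named list of three [grade_profile()]s (`G1`, `G2`, `G3`).
#' @export
default_grade_profiles <- function() {
  list(
    G1 = grade_profile("G1",
      tumor_hu_art = c(121.90, 25), tumor_hu_port = c(103.83, 12),
      necrosis_fraction = 0.02, necrosis_hu_delta = -15,
      necrosis_sd = 12, viable_sd = 12,
      irregular_margin_prob = 1 / 31, lesion_radius_mm = c(22, 4),
      qualitative_probs = list(hypodense_areas = 0.23, calcifications = 0.16,
                               mpd_dilation = 0.19, cbd_dilation = 0.19,
                               vessel_involvement = 0.06,
                               liver_metastases = 0.03,
                               heterogeneous_enhancement = 0.39)),
    G2 = grade_profile("G2",
      tumor_hu_art = c(107.86, 28), tumor_hu_port = c(98.84, 15),
      necrosis_fraction = 0.05, necrosis_hu_delta = -25,
      necrosis_sd = 12, viable_sd = 12,
      irregular_margin_prob = 16 / 52, lesion_radius_mm = c(24, 5),
      qualitative_probs = list(hypodense_areas = 0.31, calcifications = 0.21,
                               mpd_dilation = 0.21, cbd_dilation = 0.10,
                               vessel_involvement = 0.10,
                               liver_metastases = 0.06,
                               heterogeneous_enhancement = 0.63)),
    G3 = grade_profile("G3",
      tumor_hu_art = c(79.94, 14), tumor_hu_port = c(89.4, 15),
      necrosis_fraction = 0.12, necrosis_hu_delta = -70,
      necrosis_sd = 15, viable_sd = 12,
      irregular_margin_prob = 9 / 17, lesion_radius_mm = c(24, 5),
      qualitative_probs = list(hypodense_areas = 0.41, calcifications = 0.18,
                               mpd_dilation = 0.47, cbd_dilation = 0.12,
                               vessel_involvement = 0.24,
                               liver_metastases = 0.24,
                               heterogeneous_enhancement = 0.76))
  )
}

#' Exact first-order moments of a Gaussian mixture
#'
#' Mean, variance, skewness and excess kurtosis of
#' `sum_i w_i N(mu_i, sd_i^2)`, computed from the Gaussian raw moments up to
#' order four (`E X = mu`, `E X^2 = mu^2 + s^2`, `E X^3 = mu^3 + 3 mu s^2`,
#' `E X^4 = mu^4 + 6 mu^2 s^2 + 3 s^4`). This is the analytic oracle that
#' phantom ground truth and parameter-recovery tests are checked against.
#'
#' @param weights Nonnegative weights summing to 1 (tolerance 1e-9).
#' @param means,sds Component means and SDs (`sds >= 0`; 0 gives the
#'   point-mass limit).
#' @return Named list `mean`, `variance`, `skewness`, `kurtosis` (excess).
#' @export
mixture_moments <- function(weights, means, sds) {
  w <- as.numeric(weights); mu <- as.numeric(means); s <- as.numeric(sds)
  if (length(w) != length(mu) || length(w) != length(s))
    stop("weights, means and sds must have equal length")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1 (tolerance 1e-9)")
  if (any(s < 0)) stop("sds must be nonnegative")
  r1 <- sum(w * mu)
  r2 <- sum(w * (mu^2 + s^2))
  r3 <- sum(w * (mu^3 + 3 * mu * s^2))
  r4 <- sum(w * (mu^4 + 6 * mu^2 * s^2 + 3 * s^4))
  m2 <- r2 - r1^2
  m3 <- r3 - 3 * r1 * r2 + 2 * r1^3
  m4 <- r4 - 4 * r1 * r3 + 6 * r1^2 * r2 - 3 * r1^4
  if (m2 <= 0) {
    return(list(mean = r1, variance = max(m2, 0), skewness = 0, kurtosis = 0))
  }
  list(mean = r1, variance = m2, skewness = m3 / m2^1.5,
       kurtosis = m4 / m2^2 - 3)
}

#' Central moment of a Gaussian mixture (any order)
#'
#' `E[(X - mu)^k]` for `X ~ sum_i w_i N(mu_i, sd_i^2)` about the mixture mean,
#' via the binomial expansion over the component central Gaussian moments
#' (`sd^j (j-1)!!` for even `j`, 0 for odd).
#'
#' @inheritParams mixture_moments
#' @param k Moment order (>= 1).
#' @return The central moment (scalar).
#' @export
mixture_central_moment <- function(weights, means, sds, k) {
  w <- as.numeric(weights); mu <- as.numeric(means); s <- as.numeric(sds)
  m <- sum(w * mu)
  d <- mu - m
  gauss_central <- function(sd, j) {
    if (j %% 2 == 1) return(0)
    if (j == 0) return(1)
    sd^j * prod(seq(j - 1, 1, by = -2))
  }
  total <- 0
  for (i in seq_along(w)) {
    acc <- 0
    for (j in 0:k)
      acc <- acc + choose(k, j) * d[i]^(k - j) * gauss_central(s[i], j)
    total <- total + w[i] * acc
  }
  total
}

#' Asymptotic standard errors of sample first-order features
#'
#' Delta-method standard errors of the sample mean, variance, skewness and
#' excess kurtosis of `n` i.i.d. draws from a Gaussian mixture, using the
#' exact covariance of sample central moments to O(1/n):
#' `n Cov(m_j, m_k) = mu_{j+k} - mu_j mu_k + jk mu_2 mu_{j-1} mu_{k-1}
#'  - j mu_{j-1} mu_{k+1} - k mu_{k-1} mu_{j+1}`.
#' For a single Gaussian these reduce to the familiar `sqrt(6/n)` and
#' `sqrt(24/n)`; for heterogeneous mixtures (heavy histogram tails) the true
#' errors are substantially larger, which is why parameter-recovery checks
#' must not use the Gaussian formulas.
#'
#' @inheritParams mixture_moments
#' @param n Sample size.
#' @return Named list `mean`, `variance`, `skewness`, `kurtosis` of SEs.
#' @export
mixture_moment_ses <- function(weights, means, sds, n) {
  mu <- vapply(1:8, function(k)
    mixture_central_moment(weights, means, sds, k), numeric(1))
  m2 <- mu[2]; m3 <- mu[3]; m4 <- mu[4]
  cov_m <- function(j, k) {
    muj <- function(i) if (i == 0) 1 else if (i == 1) 0 else mu[i]
    (muj(j + k) - muj(j) * muj(k) + j * k * m2 * muj(j - 1) * muj(k - 1) -
       j * muj(j - 1) * muj(k + 1) - k * muj(k - 1) * muj(j + 1)) / n
  }
  v22 <- cov_m(2, 2); v33 <- cov_m(3, 3); v32 <- cov_m(3, 2)
  v44 <- cov_m(4, 4); v42 <- cov_m(4, 2)
  a3 <- m2^-1.5; a2s <- -1.5 * m3 * m2^-2.5
  var_skew <- a3^2 * v33 + 2 * a3 * a2s * v32 + a2s^2 * v22
  a4 <- m2^-2; a2k <- -2 * m4 * m2^-3
  var_kurt <- a4^2 * v44 + 2 * a4 * a2k * v42 + a2k^2 * v22
  list(mean = sqrt(m2 / n), variance = sqrt(max(v22, 0)),
       skewness = sqrt(max(var_skew, 0)), kurtosis = sqrt(max(var_kurt, 0)))
}

#' Phantom grid specification
#'
#' @param dim Integer length-3 grid dimensions `(nx, ny, nz)`.
#' @param spacing Voxel spacing `(x, y, z)` mm. The default 1 x 1 x 5 mm
#'   matches the 5 mm analysis slice thickness, so generated studies need no
#'   further through-plane resampling (resampling would low-pass the voxel
#'   noise and detach the sample from its analytic mixture ground truth).
#' @return A list with `dim`, `spacing`, `origin`.
#' @export
phantom_grid <- function(dim = c(96L, 96L, 20L), spacing = c(1, 1, 5)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 8L)) stop("grid dim must be 3 values >= 8")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) stop("spacing must be > 0")
  list(dim = dim, spacing = spacing, origin = c(0, 0, 0))
}

# fixed anatomy layout, as fractions of the in-plane extent
PHANTOM_LAYOUT <- list(
  aorta_frac = c(0.15, 0.20), aorta_radius = 9,
  portal_frac = c(0.85, 0.80), portal_radius = 7,
  pancreas_roi_frac = c(0.50, 0.12), pancreas_roi_radius = 6
)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# deterministic per-patient seed from a master seed (documented counter
# scheme; all arithmetic stays below 2^53 so it is exact in doubles)
derive_seed <- function(master_seed, i) {
  as.integer(((master_seed %% 2147483629) * 48271 + i * 1103515245) %%
               2147483629)
}

#' Generate one phantom lesion study
#'
#' Builds the multiphase volumes, the tumor mask, the measurement-ROI sidecar
#' and the analytic ground truth for a single phantom patient. Deterministic
#' given `seed` (the function seeds R's RNG).
#'
#' The measurement ROI for the tumor is placed at the lesion center on its
#' central slice and necrotic blobs are kept out of that disk, mirroring the
#' clinical protocol of measuring in enhancing tissue away from vessels,
#' calcifications and overtly cystic/necrotic areas; the true tumor
#' attenuation for the ROI is therefore the viable-component mean, while the
#' texture ground truth is the full two-component mixture.
#'
#' @param profile A [grade_profile()].
#' @param grid A [phantom_grid()].
#' @param seed Integer seed.
#' @param phases Subset of `c("precontrast", "pancreatic", "portal")` to
#'   synthesize (the pancreatic phase is always generated; restricting phases
#'   speeds up large simulation studies).
#' @return List with `volumes` (named list of [ct_volume()]), `mask`
#'   ([ct_mask()]), `rois` (list of [circular_roi()]), and `truth` (grade,
#'   realized mixture per phase, analytic moments via [mixture_moments()],
#'   true measurement set, qualitative flags, lesion size, seed).
#' @export
generate_lesion <- function(profile, grid = phantom_grid(), seed,
                            phases = PHASES) {
  stopifnot(inherits(profile, "grade_profile"))
  phases <- unique(c(match.arg(phases, PHASES, several.ok = TRUE),
                     "pancreatic"))
  set.seed(seed)
  d <- grid$dim; sp <- grid$spacing
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  xs <- (seq_len(nx) - 1) * sp[1]
  ys <- (seq_len(ny) - 1) * sp[2]
  zs <- (seq_len(nz) - 1) * sp[3]
  cx <- mean(range(xs)); cy <- mean(range(ys)); cz <- mean(range(zs))

  # lesion geometry ---------------------------------------------------------
  r_max <- 0.27 * min(max(xs), max(ys))
  r_xy <- clamp(stats::rnorm(1, profile$lesion_radius_mm[1],
                             profile$lesion_radius_mm[2]), 12, r_max)
  r_z <- clamp(0.8 * r_xy, 1.2 * sp[3], (nz / 2 - 1.5) * sp[3])
  irregular <- stats::runif(1) < profile$irregular_margin_prob
  nd2_xy <- outer(((xs - cx) / r_xy)^2, ((ys - cy) / r_xy)^2, `+`)
  if (irregular) {
    theta <- outer(xs - cx, ys - cy, function(a, b) atan2(b, a))
    ph <- stats::runif(2, 0, 2 * pi)
    perturb <- 1 + 0.12 * (sin(3 * theta + ph[1]) +
                             0.5 * sin(5 * theta + ph[2])) / 1.5
  } else {
    perturb <- matrix(1, nx, ny)
  }
  mask_arr <- array(FALSE, dim = d)
  for (k in seq_len(nz)) {
    nd2 <- nd2_xy + ((zs[k] - cz) / r_z)^2
    mask_arr[, , k] <- nd2 <= perturb^2
  }
  if (!any(mask_arr)) stop("lesion does not fit in the phantom grid")
  n_mask <- sum(mask_arr)

  # tumor-ROI geometry (protected from necrosis) ----------------------------
  roi_r <- clamp(0.45 * r_xy, 3, 8)
  kc <- which.min(abs(zs - cz))
  c_vox <- c(1 + cy / sp[2], 1 + cx / sp[1])  # (row, col)
  inplane_mm2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  protected_xy <- inplane_mm2 <= (roi_r + 0.5)^2

  # necrosis blobs -----------------------------------------------------------
  f_target <- if (profile$necrosis_fraction > 0) {
    clamp(profile$necrosis_fraction * stats::runif(1, 0.6, 1.4), 0, 0.5)
  } else 0
  necro <- array(FALSE, dim = d)
  if (f_target > 0) {
    shell <- mask_arr
    for (k in seq_len(nz)) {
      nd2 <- nd2_xy + ((zs[k] - cz) / r_z)^2
      shell[, , k] <- mask_arr[, , k] & nd2 >= 0.45^2 & nd2 <= 0.9^2 &
        !protected_xy
    }
    cand <- which(shell)
    iter <- 0L
    while (sum(necro) < f_target * n_mask && length(cand) && iter < 200L) {
      iter <- iter + 1L
      idx <- cand[sample.int(length(cand), 1L)]
      ci <- arrayInd(idx, d)
      bc <- c(xs[ci[1]], ys[ci[2]], zs[ci[3]])
      br <- stats::runif(1, 2.5, 6.5)
      bx <- which(abs(xs - bc[1]) <= br)
      by <- which(abs(ys - bc[2]) <= br)
      bz <- which(abs(zs - bc[3]) <= br)
      if (!length(bx) || !length(by) || !length(bz)) next
      sub <- outer(outer((xs[bx] - bc[1])^2, (ys[by] - bc[2])^2, `+`),
                   (zs[bz] - bc[3])^2, `+`) <= br^2
      blob <- array(FALSE, dim = d)
      blob[bx, by, bz] <- sub
      necro <- necro | (blob & mask_arr)
    }
    for (k in seq_len(nz)) necro[, , k] <- necro[, , k] & !protected_xy
  }
  w_necro <- sum(necro) / n_mask

  # per-patient intensity parameters ----------------------------------------
  mu_art <- stats::rnorm(1, profile$tumor_hu_art[1], profile$tumor_hu_art[2])
  mu_port <- stats::rnorm(1, profile$tumor_hu_port[1],
                          profile$tumor_hu_port[2])
  delta_art <- min(profile$necrosis_hu_delta + stats::rnorm(1, 0, 5), -5)
  delta_port <- 0.6 * delta_art
  comp <- function(mu, delta) {
    list(weights = c(1 - w_necro, w_necro),
         means = c(mu, mu + delta),
         sds = c(profile$viable_sd, profile$necrosis_sd))
  }
  components <- list(pancreatic = comp(mu_art, delta_art),
                     portal = comp(mu_port, delta_port))

  # vessels ------------------------------------------------------------------
  lay <- PHANTOM_LAYOUT
  vc <- function(frac) c(frac[1] * max(xs), frac[2] * max(ys))
  aorta_c <- vc(lay$aorta_frac); portal_c <- vc(lay$portal_frac)
  aorta_xy <- outer((xs - aorta_c[1])^2, (ys - aorta_c[2])^2, `+`) <=
    lay$aorta_radius^2
  portal_xy <- outer((xs - portal_c[1])^2, (ys - portal_c[2])^2, `+`) <=
    lay$portal_radius^2

  phase_means <- list(
    precontrast = list(bg = 40, tumor_viable = 40, tumor_delta = 0,
                       aorta = 45, portal = 45),
    pancreatic = list(bg = profile$pancreas_hu_art, tumor_viable = mu_art,
                      tumor_delta = delta_art, aorta = profile$aorta_hu,
                      portal = 100),
    portal = list(bg = profile$pancreas_hu_port, tumor_viable = mu_port,
                  tumor_delta = delta_port, aorta = 140,
                  portal = profile$portal_vein_hu)
  )
  bg_sd <- 7; vessel_sd <- 5
  volumes <- list()
  for (ph in PHASES) {
    if (!ph %in% phases) next
    pm <- phase_means[[ph]]
    vox <- array(stats::rnorm(prod(d), pm$bg, bg_sd), dim = d)
    n_a <- sum(aorta_xy); n_p <- sum(portal_xy)
    for (k in seq_len(nz)) {
      sl <- vox[, , k]
      sl[aorta_xy] <- stats::rnorm(n_a, pm$aorta, vessel_sd)
      sl[portal_xy] <- stats::rnorm(n_p, pm$portal, vessel_sd)
      vox[, , k] <- sl
    }
    if (ph == "precontrast") {
      vox[mask_arr] <- stats::rnorm(n_mask, pm$tumor_viable, 10)
    } else {
      viable <- mask_arr & !necro
      vox[viable] <- stats::rnorm(sum(viable), pm$tumor_viable,
                                  profile$viable_sd)
      vox[necro] <- stats::rnorm(sum(necro), pm$tumor_viable + pm$tumor_delta,
                                 profile$necrosis_sd)
    }
    volumes[[ph]] <- ct_volume(clamp(vox, HU_MIN, HU_MAX), spacing = sp,
                               origin = grid$origin, phase = ph)
  }
  mask <- ct_mask(mask_arr, spacing = sp, origin = grid$origin)

  # measurement ROIs ---------------------------------------------------------
  p_roi <- vc(lay$pancreas_roi_frac)
  rois <- list(
    circular_roi("tumor", "pancreatic", kc, c_vox, roi_r),
    circular_roi("tumor", "portal", kc, c_vox, roi_r),
    circular_roi("pancreas", "pancreatic", kc,
                 c(1 + p_roi[2] / sp[2], 1 + p_roi[1] / sp[1]),
                 lay$pancreas_roi_radius),
    circular_roi("pancreas", "portal", kc,
                 c(1 + p_roi[2] / sp[2], 1 + p_roi[1] / sp[1]),
                 lay$pancreas_roi_radius),
    circular_roi("aorta", "pancreatic", kc,
                 c(1 + aorta_c[2] / sp[2], 1 + aorta_c[1] / sp[1]), 5),
    circular_roi("portal_vein", "portal", kc,
                 c(1 + portal_c[2] / sp[2], 1 + portal_c[1] / sp[1]), 4)
  )

  # qualitative flags (sampled ground truth) --------------------------------
  qp <- profile$qualitative_probs
  bern <- function(p) stats::runif(1) < p
  enh_cat <- function(tumor, bg) {
    if (tumor > bg + 10) "hyper" else if (tumor < bg - 10) "hypo" else "iso"
  }
  flags <- list(
    margins = if (irregular) "irregular" else "sharp",
    hypodense_areas = bern(qp$hypodense_areas) || w_necro > 0.1,
    calcifications = bern(qp$calcifications),
    mpd_dilation = bern(qp$mpd_dilation),
    cbd_dilation = bern(qp$cbd_dilation),
    vessel_involvement = bern(qp$vessel_involvement),
    liver_metastases = bern(qp$liver_metastases),
    enhancement_art = enh_cat(mu_art, profile$pancreas_hu_art),
    enhancement_port = enh_cat(mu_port, profile$pancreas_hu_port),
    enhancement_pattern = if (bern(qp$heterogeneous_enhancement))
      "heterogeneous" else "homogeneous"
  )

  cmp <- components$pancreatic
  truth <- list(
    grade = profile$grade,
    seed = seed,
    lesion = list(center_mm = c(cx, cy, cz), r_xy_mm = r_xy, r_z_mm = r_z,
                  irregular = irregular),
    components = components,
    moments = mixture_moments(cmp$weights, cmp$means, cmp$sds),
    measurements = list(
      hu_tumor_art = mu_art, hu_tumor_port = mu_port,
      hu_pancreas_art = profile$pancreas_hu_art,
      hu_pancreas_port = profile$pancreas_hu_port,
      hu_aorta = profile$aorta_hu, hu_portal = profile$portal_vein_hu),
    necrosis_fraction_realized = w_necro,
    n_voxels = n_mask,
    size_mm = 2 * r_xy,
    qualitative = flags
  )
  list(volumes = volumes, mask = mask, rois = rois, truth = truth)
}

#' Generate a phantom cohort
#'
#' Generates `sum(n_per_grade)` phantom patients with per-patient seeds
#' derived deterministically from `master_seed`. When `dir` is given, each
#' patient is written as `dir/<id>/{precontrast,pancreatic,portal}.nii.gz`
#' plus `mask.nii.gz` and `rois.json`, and a `manifest.json` with the profile
#' echo, seeds and per-patient analytic ground truth is written at the cohort
#' root.
#'
#' @param n_per_grade Named or ordered integer vector `(G1, G2, G3)`; the
#'   default 31/52/17 reproduces the reference cohort composition
#'   (100 patients).
#' @param profiles Named list of [grade_profile()]s for G1, G2, G3.
#' @param master_seed Integer master seed.
#' @param dir Output directory (created), or `NULL` for no file output.
#' @param grid A [phantom_grid()].
#' @param phases Phases to synthesize (see [generate_lesion()]).
#' @param keep_volumes Keep the generated volumes/masks in the returned
#'   records (`FALSE` by default: a full cohort does not fit in memory).
#' @return Invisibly, a list with `records` (per-patient list of `patient_id`,
#'   `grade`, `seed`, `truth`, `rois`, and optionally `volumes`/`mask`) and
#'   `manifest` (the manifest written to disk).
#' @export
generate_cohort <- function(n_per_grade = c(G1 = 31L, G2 = 52L, G3 = 17L),
                            profiles = default_grade_profiles(),
                            master_seed = 1L, dir = NULL,
                            grid = phantom_grid(), phases = PHASES,
                            keep_volumes = FALSE) {
  if (length(n_per_grade) != 3L || any(n_per_grade < 1L))
    stop("`n_per_grade` must give >= 1 patient for each of G1, G2, G3")
  grades <- rep(c("G1", "G2", "G3"), times = as.integer(n_per_grade))
  if (!all(c("G1", "G2", "G3") %in% names(profiles)))
    stop("`profiles` must be a named list with G1, G2 and G3 entries")
  write_files <- !is.null(dir)
  if (write_files) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- vector("list", length(grades))
  for (i in seq_along(grades)) {
    g <- grades[i]
    id <- sprintf("p%03d", i)
    seed_i <- derive_seed(master_seed, i)
    les <- generate_lesion(profiles[[g]], grid = grid, seed = seed_i,
                           phases = phases)
    rec <- list(patient_id = id, grade = g, seed = seed_i,
                truth = les$truth, rois = les$rois)
    if (keep_volumes) {
      rec$volumes <- les$volumes
      rec$mask <- les$mask
    }
    if (write_files) {
      pdir <- file.path(dir, id)
      dir.create(pdir, showWarnings = FALSE)
      for (ph in names(les$volumes))
        write_volume(les$volumes[[ph]], file.path(pdir, paste0(ph, ".nii.gz")))
      write_mask(les$mask, file.path(pdir, "mask.nii.gz"))
      write_rois(les$rois, file.path(pdir, "rois.json"))
    }
    records[[i]] <- rec
  }
  manifest <- list(
    master_seed = master_seed,
    n_per_grade = as.list(stats::setNames(as.integer(n_per_grade),
                                          c("G1", "G2", "G3"))),
    grid = grid,
    phases = phases,
    profiles = lapply(profiles, unclass),
    note = paste("Vessel/pancreas attenuations and heterogeneity parameters",
                 "are calibration choices, not measured cohort values."),
    patients = lapply(records, function(r)
      list(patient_id = r$patient_id, grade = r$grade, seed = r$seed,
           truth = r$truth))
  )
  if (write_files) {
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(records = records, manifest = manifest))
}
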