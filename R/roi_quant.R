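# Circular-ROI attenuation measurement and the enhancement/permeability
# ratios. The measurement protocol mirrors clinical practice: a circular ROI
# is drawn on one slice per structure (tumor, adjacent pancreas, aorta,
# portal vein) and copied unchanged to the other contrast phases.

ROI_STRUCTURES <- c("tumor", "pancreas", "aorta", "portal_vein")

#' Circular 2D measurement ROI
#'
#' A disk on a single axial slice, defined in voxel coordinates (1-based) with
#' a physical radius in mm, tagged with the structure it measures and the
#' contrast phase it was drawn on.
#'
#' @param structure One of `"tumor"`, `"pancreas"`, `"aorta"`, `"portal_vein"`.
#' @param phase Contrast phase the ROI is drawn on.
#' @param slice_index Axial slice (1-based, z index).
#' @param center Length-2 numeric `(row, col)` = (y index, x index), 1-based;
#'   fractional centers are allowed.
#' @param radius Disk radius in mm (> 0).
#' @return An object of class `circular_roi`.
#' @export
circular_roi <- function(structure, phase, slice_index, center, radius) {
  structure <- match.arg(structure, ROI_STRUCTURES)
  phase <- match.arg(phase, PHASES)
  if (!is.finite(radius) || radius <= 0) stop("`radius` must be > 0 mm")
  center <- as.numeric(center)
  if (length(center) != 2L || !all(is.finite(center)))
    stop("`center` must be finite (row, col) voxel coordinates")
  slice_index <- as.integer(slice_index)
  if (!is.finite(slice_index) || slice_index < 1L)
    stop("`slice_index` must be a positive slice number")
  structure(
    list(structure = structure, phase = phase, slice_index = slice_index,
         center = center, radius = radius),
    class = "circular_roi"
  )
}

# logical in-plane membership matrix: voxel centers within `radius` mm of the
# ROI center, using world (mm) distances so anisotropic pixels are handled.
roi_disk_membership <- function(dim_xy, spacing_xy, center_rc, radius_mm) {
  # center_rc = (row, col) = (y, x); voxel array is [x, y]
  dx <- (seq_len(dim_xy[1]) - center_rc[2]) * spacing_xy[1]
  dy <- (seq_len(dim_xy[2]) - center_rc[1]) * spacing_xy[2]
  outer(dx^2, dy^2, `+`) <= radius_mm^2
}

#' Mean HU inside a circular ROI
#'
#' Arithmetic mean over all voxels of the ROI's slice whose in-plane center
#' lies within `radius` mm of the ROI center. ROIs that leave the image or
#' cover fewer than `min_voxels` voxels are rejected: a mean over a handful of
#' voxels is not a meaningful attenuation measurement.
#'
#' @param vol A [ct_volume()] of the matching phase.
#' @param roi A [circular_roi()].
#' @param min_voxels Minimum member-voxel count (default 5).
#' @return Mean attenuation in HU (scalar).
#' @export
roi_mean <- function(vol, roi, min_voxels = 5L) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "circular_roi"))
  d <- dim(vol$voxels)
  k <- roi$slice_index
  if (k < 1L || k > d[3]) stop("ROI slice_index ", k, " outside volume (1..", d[3], ")")
  cr <- roi$center
  if (cr[1] < 1 || cr[1] > d[2] || cr[2] < 1 || cr[2] > d[1])
    stop("ROI center lies outside the image")
  r_vox <- roi$radius / vol$spacing[1:2]
  if (cr[2] - r_vox[1] < 0.5 || cr[2] + r_vox[1] > d[1] + 0.5 ||
      cr[1] - r_vox[2] < 0.5 || cr[1] + r_vox[2] > d[2] + 0.5)
    stop("ROI disk extends beyond the image boundary")
  inside <- roi_disk_membership(d[1:2], vol$spacing[1:2], cr, roi$radius)
  n <- sum(inside)
  if (n < min_voxels)
    stop("ROI covers only ", n, " voxels (< ", min_voxels,
         "); enlarge the radius")
  mean(vol$voxels[, , k][inside])
}

#' Copy an ROI to another contrast phase
#'
#' Clinical workstations copy a drawn ROI verbatim to the co-registered
#' acquisitions of the other phases. This is a pure relabeling: identical
#' center, slice and radius. If reference volumes are supplied their grid
#' geometry must match exactly; no registration is attempted.
#'
#' @param roi A [circular_roi()].
#' @param target_phase Phase label for the copy.
#' @param source_vol,target_vol Optional [ct_volume()]s used to verify that
#'   the two phases share geometry (error on mismatch).
#' @return A [circular_roi()] on `target_phase`.
#' @export
copy_roi_across_phases <- function(roi, target_phase,
                                   source_vol = NULL, target_vol = NULL) {
  stopifnot(inherits(roi, "circular_roi"))
  target_phase <- match.arg(target_phase, PHASES)
  if (!is.null(source_vol) && !is.null(target_vol) &&
      !same_geometry(source_vol, target_vol))
    stop_geometry_mismatch("source and target phase volumes")
  circular_roi(roi$structure, target_phase, roi$slice_index, roi$center,
               roi$radius)
}

#' Six-value ROI measurement set
#'
#' The per-patient attenuation measurements the ratio panel is built from:
#' tumor on the pancreatic (arterial) and portal phases, adjacent pancreatic
#' parenchyma on both phases, aorta on the pancreatic phase and portal vein on
#' the portal phase (each vessel measured in the phase where it is maximally
#' enhanced). All arguments are vectorized (one element per patient).
#'
#' @param hu_tumor_art,hu_tumor_port Tumor mean HU, pancreatic/portal phase.
#' @param hu_pancreas_art,hu_pancreas_port Parenchyma mean HU per phase.
#' @param hu_aorta Aortic mean HU (pancreatic phase).
#' @param hu_portal Portal-vein mean HU (portal phase).
#' @return An object of class `measurement_set` (a list of numeric vectors).
#' @export
measurement_set <- function(hu_tumor_art, hu_tumor_port, hu_pancreas_art,
                            hu_pancreas_port, hu_aorta, hu_portal) {
  m <- list(hu_tumor_art = as.numeric(hu_tumor_art),
            hu_tumor_port = as.numeric(hu_tumor_port),
            hu_pancreas_art = as.numeric(hu_pancreas_art),
            hu_pancreas_port = as.numeric(hu_pancreas_port),
            hu_aorta = as.numeric(hu_aorta),
            hu_portal = as.numeric(hu_portal))
  n <- unique(lengths(m))
  if (length(n) != 1L) stop("all six measurements must have equal length")
  for (nm in names(m)) if (any(!is.finite(m[[nm]])))
    stop("non-finite values in ", nm)
  if (any(m$hu_aorta <= 0)) stop("hu_aorta must be strictly positive")
  if (any(m$hu_portal <= 0)) stop("hu_portal must be strictly positive")
  structure(m, class = "measurement_set")
}

#' Enhancement and permeability ratio panel
#'
#' Computes the seven dimensionless indices used to normalize attenuation
#' across examinations:
#' \describe{
#'   \item{tumor_parenchyma_ratio_1}{`hu_tumor_art / hu_pancreas_art`}
#'   \item{tumor_parenchyma_ratio_2}{`hu_tumor_port / hu_pancreas_port`}
#'   \item{tumor_arterial_ratio}{`hu_tumor_art / hu_aorta`}
#'   \item{tumor_venous_ratio}{`hu_tumor_port / hu_portal`}
#'   \item{tumor_permeability_ratio_1}{`(hu_tumor_art + hu_tumor_port) / hu_aorta`}
#'   \item{tumor_permeability_ratio_2}{`(hu_tumor_port - hu_tumor_art) / hu_aorta`}
#'   \item{tumor_permeability_ratio_3}{`hu_tumor_art / hu_tumor_port`}
#' }
#' By construction `ratio_1 - ratio_2 = 2 * tumor_arterial_ratio` exactly.
#' Denominators smaller than `denom_guard` HU in magnitude signal corrupt
#' measurements (enhanced vessels and parenchyma are far above 1 HU) and raise
#' an error naming the offending measurement.
#'
#' @param m A [measurement_set()].
#' @param denom_guard Minimum |denominator| in HU (default 1).
#' @return A data.frame with the seven ratio columns, one row per patient.
#' @export
compute_ratios <- function(m, denom_guard = 1) {
  stopifnot(inherits(m, "measurement_set"))
  guard <- function(x, name) {
    if (any(abs(x) < denom_guard))
      stop("denominator ", name, " below ", denom_guard,
           " HU in magnitude; refusing to divide", call. = FALSE)
    x
  }
  panc_art <- guard(m$hu_pancreas_art, "hu_pancreas_art")
  panc_port <- guard(m$hu_pancreas_port, "hu_pancreas_port")
  aorta <- guard(m$hu_aorta, "hu_aorta")
  portal <- guard(m$hu_portal, "hu_portal")
  tum_port <- guard(m$hu_tumor_port, "hu_tumor_port")
  data.frame(
    tumor_parenchyma_ratio_1 = m$hu_tumor_art / panc_art,
    tumor_parenchyma_ratio_2 = m$hu_tumor_port / panc_port,
    tumor_arterial_ratio = m$hu_tumor_art / aorta,
    tumor_venous_ratio = m$hu_tumor_port / portal,
    tumor_permeability_ratio_1 = (m$hu_tumor_art + m$hu_tumor_port) / aorta,
    tumor_permeability_ratio_2 = (m$hu_tumor_port - m$hu_tumor_art) / aorta,
    tumor_permeability_ratio_3 = m$hu_tumor_art / tum_port
  )
}

# ---------------------------------------------------------------------------
# ROI sidecar JSON

#' Write / read the ROI sidecar
#'
#' The sidecar is a JSON array of objects with fields `structure`, `phase`,
#' `slice_index`, `center_row`, `center_col` (voxel coordinates, 1-based) and
#' `radius_mm`, one per drawn ROI.
#'
#' @param rois A list of [circular_roi()] objects.
#' @param path JSON path.
#' @return `write_rois()`: `path` invisibly; `read_rois()`: list of
#'   [circular_roi()].
#' @export
write_rois <- function(rois, path) {
  stopifnot(length(rois) > 0L,
            all(vapply(rois, inherits, logical(1), "circular_roi")))
  df <- data.frame(
    structure = vapply(rois, `[[`, character(1), "structure"),
    phase = vapply(rois, `[[`, character(1), "phase"),
    slice_index = vapply(rois, `[[`, integer(1), "slice_index"),
    center_row = vapply(rois, function(r) r$center[1], numeric(1)),
    center_col = vapply(rois, function(r) r$center[2], numeric(1)),
    radius_mm = vapply(rois, `[[`, numeric(1), "radius")
  )
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname write_rois
#' @export
read_rois <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(df)), function(i) {
    circular_roi(df$structure[i], df$phase[i], df$slice_index[i],
                 c(df$center_row[i], df$center_col[i]), df$radius_mm[i])
  })
}
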