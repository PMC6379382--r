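# Volume containers and NIfTI-1 input/output.
#
# Intensities are always Hounsfield Units (HU) in memory; any scl_slope /
# scl_inter stored in a NIfTI header is applied on read. Geometry is restricted
# to axis-aligned grids: spacing (x, y, z) in mm plus a world origin. Voxel
# arrays are indexed [i, j, k] = (x, y, z), 1-based as usual in R.

PHASES <- c("precontrast", "pancreatic", "portal")

HU_MIN <- -1024
HU_MAX <- 4095

#' CT volume constructor
#'
#' Bundles a 3D voxel array in Hounsfield Units with its grid geometry and a
#' contrast-phase label. The world position of voxel `(i, j, k)` is
#' `origin + (i - 1, j - 1, k - 1) * spacing` (axis-aligned grids only).
#'
#' @param voxels Numeric 3D array of attenuation values in HU.
#' @param spacing Numeric length-3, voxel spacing `(x, y, z)` in mm, all > 0.
#' @param origin Numeric length-3 world coordinate (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @param phase One of `"precontrast"`, `"pancreatic"`, `"portal"`.
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing, origin = c(0, 0, 0), phase) {
  phase <- match.arg(phase, PHASES)
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array, got ", length(dim(voxels)), " dims")
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("volume contains non-finite voxel values")
  if (min(voxels) < HU_MIN || max(voxels) > HU_MAX)
    stop(sprintf("voxel values outside the HU range [%d, %d]", HU_MIN, HU_MAX))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive mm values")
  origin <- as.numeric(origin)
  if (length(origin) != 3L || !all(is.finite(origin)))
    stop("`origin` must be three finite mm values")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, phase = phase),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %dx%dx%d voxels, spacing %.3gx%.3gx%.3g mm, phase %s, HU [%.1f, %.1f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], x$phase,
    min(x$voxels), max(x$voxels)
  ))
  invisible(x)
}

#' 3D binary mask constructor
#'
#' A tumor segmentation on the same grid as its paired [ct_volume()]. Nonzero
#' input voxels are inside; the mask must contain at least one voxel.
#'
#' @param voxels Logical or numeric 3D array; nonzero = inside.
#' @inheritParams ct_volume
#' @return An object of class `ct_mask`.
#' @export
ct_mask <- function(voxels, spacing, origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  storage.mode(voxels) <- "logical"
  if (anyNA(voxels)) stop("mask contains NA voxels")
  if (!any(voxels)) stop("mask is empty: at least one interior voxel required")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive mm values")
  origin <- as.numeric(origin)
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin),
    class = "ct_mask"
  )
}

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_mask> %dx%dx%d grid, %d voxels inside\n",
              d[1], d[2], d[3], sum(x$voxels)))
  invisible(x)
}

# Geometry equality for volume/volume or volume/mask pairs. Tolerance is tight:
# a real mismatch (different scanner grid) is orders of magnitude larger.
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$voxels), dim(b$voxels)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol
}

stop_geometry_mismatch <- function(what = "objects") {
  stop(what, " do not share grid geometry (shape/spacing/origin); ",
       "no implicit resampling is performed", call. = FALSE)
}

# ---------------------------------------------------------------------------
# NIfTI-1 single-file I/O (.nii / .nii.gz). Only what this pipeline needs:
# little- or big-endian read, axis-aligned geometry, datatypes uint8 / int16 /
# int32 / float32 / float64 / int8 / uint16, scl slope/intercept applied on
# read. Written files are float64 (volumes) or uint8 (masks), little-endian,
# sform only, so round-trips are bit-exact.

NIFTI_DT <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

open_nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

read_nifti_raw <- function(path) {
  con <- open_nii_con(path, "rb")
  on.exit(close(con))
  hdr_bytes <- readBin(con, "raw", n = 348L)
  if (length(hdr_bytes) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_bytes[1:4], "integer", size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_bytes[1:4], "integer", size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop(path, " is not a NIfTI-1 file")
  }
  magic <- rawToChar(hdr_bytes[345:347])
  if (!magic %in% c("n+1", "ni1")) stop(path, " has no NIfTI magic string")
  rd <- function(off, what, n, size) {
    readBin(hdr_bytes[(off + 1):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dims     <- rd(40L, "integer", 8L, 2L)
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim   <- rd(76L, "double", 8L, 4L)
  vox_off  <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform    <- rd(254L, "integer", 1L, 2L)
  qoffset  <- rd(268L, "double", 3L, 4L)
  srow     <- matrix(rd(280L, "double", 12L, 4L), nrow = 3L, byrow = TRUE)
  ndim <- dims[1]
  if (ndim < 3L) stop(path, ": expected a 3D image, got ", ndim, " dims")
  if (ndim > 3L && any(dims[5:(ndim + 1L)] > 1L))
    stop(path, ": only scalar 3D images are supported")
  d <- pmax(dims[2:4], 1L)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt)) stop(path, ": unsupported NIfTI datatype code ", datatype)
  # skip to the data offset (gz connections cannot seek reliably)
  skip <- as.integer(round(vox_off)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  n <- prod(d)
  vox <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                 endian = endian)
  if (length(vox) < n) stop(path, ": truncated voxel data")
  if (dt$size == 2L && !dt$signed) { # readBin cannot do unsigned 16-bit
    vox <- ifelse(vox < 0, vox + 65536, vox)
  }
  vox <- as.double(vox)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vox <- vox * scl_slope + scl_inter
  }
  spacing <- abs(pixdim[2:4])
  origin <- if (sform > 0L) srow[, 4L] else qoffset
  list(voxels = array(vox, dim = d), spacing = spacing, origin = origin)
}

#' Read a CT volume from NIfTI-1
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`), applies the stored
#' intensity scaling (`scl_slope`/`scl_inter`) so that the returned voxels are
#' in HU, and attaches the given contrast-phase label. Only axis-aligned
#' scalar 3D images are supported; DICOM series are out of scope and rejected
#' with an explicit error.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param phase Contrast-phase label for the returned volume.
#' @return A [ct_volume()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path, phase) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (dir.exists(path))
    stop("DICOM series directories are not supported; convert to NIfTI first")
  raw <- read_nifti_raw(path)
  ct_volume(raw$voxels, spacing = raw$spacing, origin = raw$origin,
            phase = phase)
}

#' Read a 3D tumor mask from NIfTI-1
#'
#' @inheritParams read_volume
#' @return A [ct_mask()]; nonzero stored voxels are inside.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read_nifti_raw(path)
  ct_mask(raw$voxels != 0, spacing = raw$spacing, origin = raw$origin)
}

write_nifti_raw <- function(voxels, spacing, origin, path, datatype) {
  dt <- NIFTI_DT[[as.character(datatype)]]
  d <- dim(voxels)
  con <- open_nii_con(path, "wb")
  on.exit(close(con))
  wb <- function(x, size) writeBin(x, con, size = size, endian = "little")
  wraw <- function(n) writeBin(raw(n), con)
  wb(348L, 4L)                              # sizeof_hdr
  wraw(10L + 18L + 4L + 2L + 1L + 1L)       # data_type..dim_info
  wb(as.integer(c(3L, d, 1L, 1L, 1L, 1L)), 2L)  # dim
  wb(numeric(3L), 4L)                       # intent_p1..3
  wb(c(0L, as.integer(datatype), 8L * dt$size, 0L), 2L)  # intent..slice_start
  wb(c(1, spacing, 1, 1, 1, 1), 4L)         # pixdim
  wb(c(352, 1, 0), 4L)                      # vox_offset, scl_slope, scl_inter
  wb(0L, 2L); wraw(1L)                      # slice_end, slice_code
  writeBin(as.raw(10L), con)                # xyzt_units: mm | sec
  wb(numeric(4L), 4L)                       # cal_max..toffset
  wb(integer(2L), 4L)                       # glmax, glmin
  wraw(80L + 24L)                           # descrip, aux_file
  wb(c(0L, 1L), 2L)                         # qform_code 0, sform_code 1
  wb(numeric(6L), 4L)                       # quatern, qoffset
  srow <- rbind(c(spacing[1], 0, 0, origin[1]),
                c(0, spacing[2], 0, origin[2]),
                c(0, 0, spacing[3], origin[3]))
  wb(as.numeric(t(srow)), 4L)
  wraw(16L)                                 # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)  # magic
  wraw(4L)                                  # extension flag
  if (dt$what == "integer") {
    wb(as.integer(round(voxels)), dt$size)
  } else {
    wb(as.numeric(voxels), dt$size)
  }
  invisible(path)
}

#' Write a CT volume to NIfTI-1
#'
#' Voxels are stored as float64 with identity intensity scaling, so
#' `read_volume(write_volume(v))` reproduces `v$voxels` exactly.
#'
#' @param vol A [ct_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  write_nifti_raw(vol$voxels, vol$spacing, vol$origin, path, datatype = 64L)
}

#' Write a 3D mask to NIfTI-1 (uint8, 1 = inside)
#'
#' @param mask A [ct_mask()].
#' @inheritParams write_volume
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "ct_mask"))
  write_nifti_raw(mask$voxels + 0L, mask$spacing, mask$origin, path,
                  datatype = 2L)
}

# ---------------------------------------------------------------------------
# Slice-thickness standardization

#' Resample a volume to a target slice thickness
#'
#' Standardizes the through-plane resolution before texture analysis, the way
#' clinical workstations reconstruct thick slices: linear interpolation along
#' z only, in-plane grid untouched. Output slice k (1-based) is centered at
#' world z `origin_z + (k - 1) * target_thickness`; the output covers the
#' original z extent (slice centers beyond the last input center are dropped).
#'
#' @param vol A [ct_volume()].
#' @param target_thickness New z spacing in mm (> 0). Default 5, the common
#'   thick-slice reconstruction used for first-order texture work.
#' @return A [ct_volume()] with z spacing `target_thickness`.
#' @export
resample_slices <- function(vol, target_thickness = 5) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.finite(target_thickness) || target_thickness <= 0)
    stop("`target_thickness` must be a positive thickness in mm")
  dz <- vol$spacing[3]
  if (isTRUE(all.equal(dz, target_thickness))) return(vol)
  d <- dim(vol$voxels)
  nz <- d[3]
  extent <- (nz - 1) * dz
  if (nz == 1L && target_thickness != dz)
    stop("cannot resample a single-slice volume along z")
  n_out <- floor(extent / target_thickness + 1e-9) + 1L
  if (n_out < 1L) n_out <- 1L
  z_out <- (seq_len(n_out) - 1) * target_thickness  # relative to origin_z
  pos <- z_out / dz                                  # fractional input index
  k0 <- pmin(floor(pos), nz - 2)                     # lower slice, 0-based
  k0 <- pmax(k0, 0)
  w <- pos - k0                                      # weight of upper slice
  out <- array(0, dim = c(d[1], d[2], n_out))
  for (k in seq_len(n_out)) {
    lo <- k0[k] + 1L
    out[, , k] <- (1 - w[k]) * vol$voxels[, , lo] + w[k] * vol$voxels[, , lo + 1L]
  }
  ct_volume(out, spacing = c(vol$spacing[1:2], target_thickness),
            origin = vol$origin, phase = vol$phase)
}

# ---------------------------------------------------------------------------
# Cohort table I/O

QUAL_FLAG_COLS <- c("margins", "hypodense_areas", "calcifications",
                    "mpd_dilation", "cbd_dilation", "vessel_involvement",
                    "liver_metastases", "enhancement_art", "enhancement_port",
                    "enhancement_pattern")

MEASUREMENT_COLS <- c("hu_tumor_art", "hu_tumor_port", "hu_pancreas_art",
                      "hu_pancreas_port", "hu_aorta", "hu_portal")

RATIO_COLS <- c("tumor_parenchyma_ratio_1", "tumor_parenchyma_ratio_2",
                "tumor_arterial_ratio", "tumor_venous_ratio",
                "tumor_permeability_ratio_1", "tumor_permeability_ratio_2",
                "tumor_permeability_ratio_3")

TEXTURE_COLS <- c("mean_value", "variance", "skewness", "kurtosis", "entropy")

#' Canonical cohort table column order
#'
#' One row per patient: identifier, grade, lesion size, the qualitative
#' imaging flags, the six ROI measurements (HU), the seven enhancement /
#' permeability ratios, the five first-order texture features, the tumor voxel
#' count, and a QC flag.
#'
#' @return Character vector of column names in their documented order.
#' @export
cohort_columns <- function() {
  c("patient_id", "grade", "size_mm", QUAL_FLAG_COLS, MEASUREMENT_COLS,
    RATIO_COLS, TEXTURE_COLS, "n_voxels", "qc_fail")
}

#' Write a cohort table to CSV
#'
#' @param records A data.frame with (at least) the [cohort_columns()] columns,
#'   one row per patient with unique `patient_id`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("`records` must be a non-empty data.frame of patient rows")
  missing_cols <- setdiff(cohort_columns(), names(records))
  if (length(missing_cols))
    stop("cohort table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(records$patient_id))
    stop("duplicate patient_id values in cohort table")
  records <- records[, cohort_columns()]
  utils::write.csv(format_cohort_numeric(records), path, row.names = FALSE,
                   quote = TRUE, na = "NA")
  invisible(path)
}

# full-precision text representation so write -> read is lossless
format_cohort_numeric <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df[num] <- lapply(df[num], function(x) ifelse(x %in% c("NA", "nan"), NA, x))
  df
}

#' Read a cohort table written by [write_cohort_table()]
#'
#' @param path CSV path.
#' @return A data.frame in [cohort_columns()] order with typed columns.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(cohort_columns(), names(df))
  if (length(missing_cols))
    stop("cohort CSV is missing columns: ", paste(missing_cols, collapse = ", "))
  num_cols <- c("size_mm", MEASUREMENT_COLS, RATIO_COLS, TEXTURE_COLS)
  df[num_cols] <- lapply(df[num_cols], as.numeric)
  df$n_voxels <- as.integer(df$n_voxels)
  df$qc_fail <- as.logical(df$qc_fail)
  bool_cols <- setdiff(QUAL_FLAG_COLS,
                       c("margins", "enhancement_art", "enhancement_port",
                         "enhancement_pattern"))
  df[bool_cols] <- lapply(df[bool_cols], as.logical)
  df[, cohort_columns()]
}
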