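# Orchestration: simulate -> extract -> analyze. Each stage composes only the
# public operations of the other modules and isolates per-patient failures
# (a failed patient is flagged, the cohort run continues).

#' Resample a mask to a target slice thickness (nearest neighbor)
#'
#' Companion to [resample_slices()] for binary masks: output slice k takes the
#' nearest input slice, in-plane untouched. Used by the extraction stage when
#' a study was acquired at a different thickness than the texture standard;
#' texture operations themselves never resample implicitly.
#'
#' @param mask A [ct_mask()].
#' @param target_thickness New z spacing in mm (> 0).
#' @return A [ct_mask()].
#' @export
resample_mask <- function(mask, target_thickness = 5) {
  stopifnot(inherits(mask, "ct_mask"))
  if (!is.finite(target_thickness) || target_thickness <= 0)
    stop("`target_thickness` must be a positive thickness in mm")
  dz <- mask$spacing[3]
  if (isTRUE(all.equal(dz, target_thickness))) return(mask)
  d <- dim(mask$voxels)
  extent <- (d[3] - 1) * dz
  n_out <- floor(extent / target_thickness + 1e-9) + 1L
  src <- pmin(pmax(round((seq_len(n_out) - 1) * target_thickness / dz) + 1L,
                   1L), d[3])
  ct_mask(mask$voxels[, , src, drop = FALSE],
          spacing = c(mask$spacing[1:2], target_thickness),
          origin = mask$origin)
}

find_roi <- function(rois, structure, phase) {
  for (r in rois) if (r$structure == structure && r$phase == phase) return(r)
  NULL
}

#' Extract the full feature row of one study
#'
#' Runs the measurement protocol on one patient: circular-ROI means on the
#' native-resolution phases (tumor and pancreas on both post-contrast phases,
#' aorta on the pancreatic phase, portal vein on the portal phase; the tumor
#' ROI is copied across phases if the sidecar holds only the pancreatic one),
#' the seven ratios, and the first-order texture panel of the masked tumor on
#' the pancreatic phase standardized to `thickness` mm slices.
#'
#' @param volumes Named list of [ct_volume()]s; `pancreatic` and `portal`
#'   phases are required.
#' @param mask Tumor [ct_mask()] on the pancreatic-phase grid.
#' @param rois List of [circular_roi()] (see [read_rois()]).
#' @param cfg A [binning_config()].
#' @param thickness Texture slice thickness in mm (default 5).
#' @return One-row data.frame: six measurements, seven ratios, five texture
#'   features, `n_voxels`.
#' @export
extract_study_features <- function(volumes, mask, rois,
                                   cfg = binning_config(), thickness = 5) {
  for (ph in c("pancreatic", "portal"))
    if (is.null(volumes[[ph]])) stop("missing ", ph, " phase volume")
  panc <- volumes$pancreatic; port <- volumes$portal
  tum_art <- find_roi(rois, "tumor", "pancreatic")
  if (is.null(tum_art)) stop("sidecar lacks a tumor ROI on the pancreatic phase")
  tum_port <- find_roi(rois, "tumor", "portal")
  if (is.null(tum_port))
    tum_port <- copy_roi_across_phases(tum_art, "portal", panc, port)
  pan_art <- find_roi(rois, "pancreas", "pancreatic")
  if (is.null(pan_art)) stop("sidecar lacks a pancreas ROI on the pancreatic phase")
  pan_port <- find_roi(rois, "pancreas", "portal")
  if (is.null(pan_port))
    pan_port <- copy_roi_across_phases(pan_art, "portal", panc, port)
  ao <- find_roi(rois, "aorta", "pancreatic")
  pv <- find_roi(rois, "portal_vein", "portal")
  if (is.null(ao) || is.null(pv))
    stop("sidecar lacks the aorta (pancreatic) or portal-vein (portal) ROI")
  m <- measurement_set(
    hu_tumor_art = roi_mean(panc, tum_art),
    hu_tumor_port = roi_mean(port, tum_port),
    hu_pancreas_art = roi_mean(panc, pan_art),
    hu_pancreas_port = roi_mean(port, pan_port),
    hu_aorta = roi_mean(panc, ao),
    hu_portal = roi_mean(port, pv)
  )
  ratios <- compute_ratios(m)
  panc5 <- resample_slices(panc, thickness)
  mask5 <- resample_mask(mask, thickness)
  tex <- texture_from_study(panc5, mask5, cfg)
  cbind(as.data.frame(unclass(m)), ratios,
        data.frame(mean_value = tex$mean_value, variance = tex$variance,
                   skewness = tex$skewness, kurtosis = tex$kurtosis,
                   entropy = tex$entropy, n_voxels = tex$n_voxels))
}

empty_feature_row <- function() {
  row <- as.data.frame(as.list(stats::setNames(
    rep(NA_real_, length(c(MEASUREMENT_COLS, RATIO_COLS, TEXTURE_COLS))),
    c(MEASUREMENT_COLS, RATIO_COLS, TEXTURE_COLS))))
  row$n_voxels <- NA_integer_
  row
}

truth_flag_row <- function(truth) {
  q <- truth$qualitative
  data.frame(margins = q$margins, hypodense_areas = q$hypodense_areas,
             calcifications = q$calcifications,
             mpd_dilation = q$mpd_dilation, cbd_dilation = q$cbd_dilation,
             vessel_involvement = q$vessel_involvement,
             liver_metastases = q$liver_metastases,
             enhancement_art = q$enhancement_art,
             enhancement_port = q$enhancement_port,
             enhancement_pattern = q$enhancement_pattern)
}

#' Simulate and extract a cohort in memory
#'
#' Fuses [generate_cohort()] and [extract_study_features()] without touching
#' disk: each phantom patient is generated, measured and discarded, so large
#' simulation studies (many replicate cohorts) stay within memory and time
#' budgets. With `measurements = FALSE` only the pancreatic phase is
#' synthesized and only the texture features are filled in (the measurement
#' and ratio columns are NA), roughly halving the cost for texture-only
#' studies.
#'
#' @inheritParams generate_cohort
#' @param cfg A [binning_config()].
#' @param thickness Texture slice thickness in mm.
#' @param measurements Also measure ROIs/ratios (needs the portal phase).
#' @return A cohort data.frame in [cohort_columns()] order.
#' @export
phantom_cohort_features <- function(n_per_grade = c(G1 = 31L, G2 = 52L,
                                                    G3 = 17L),
                                    profiles = default_grade_profiles(),
                                    master_seed = 1L, grid = phantom_grid(),
                                    cfg = binning_config(), thickness = 5,
                                    measurements = TRUE) {
  grades <- rep(c("G1", "G2", "G3"), times = as.integer(n_per_grade))
  phases <- if (measurements) c("pancreatic", "portal") else "pancreatic"
  rows <- vector("list", length(grades))
  for (i in seq_along(grades)) {
    seed_i <- derive_seed(master_seed, i)
    les <- generate_lesion(profiles[[grades[i]]], grid = grid, seed = seed_i,
                           phases = phases)
    if (measurements) {
      feats <- extract_study_features(les$volumes, les$mask, les$rois,
                                      cfg = cfg, thickness = thickness)
    } else {
      feats <- empty_feature_row()
      panc5 <- resample_slices(les$volumes$pancreatic, thickness)
      tex <- texture_from_study(panc5, resample_mask(les$mask, thickness), cfg)
      feats$mean_value <- tex$mean_value; feats$variance <- tex$variance
      feats$skewness <- tex$skewness; feats$kurtosis <- tex$kurtosis
      feats$entropy <- tex$entropy; feats$n_voxels <- tex$n_voxels
    }
    rows[[i]] <- cbind(
      data.frame(patient_id = sprintf("p%03d", i), grade = grades[i],
                 size_mm = les$truth$size_mm),
      truth_flag_row(les$truth), feats, data.frame(qc_fail = FALSE))
  }
  df <- do.call(rbind, rows)
  df[, cohort_columns()]
}

#' Pipeline configuration
#'
#' Reads a YAML file (or takes a list) and fills in defaults:
#' `cohort_dir`, `out_dir`, `n_per_grade` (31/52/17), `master_seed` (1),
#' `thickness` (5 mm), `n_bins` (128), `range_mode` (`mask_min_max`),
#' `alpha` (0.05), `cutoffs` (named list, optional).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(cohort_dir = "cohort", out_dir = "results",
                   n_per_grade = c(G1 = 31L, G2 = 52L, G3 = 17L),
                   master_seed = 1L, thickness = 5, n_bins = 128L,
                   range_mode = "mask_min_max", alpha = 0.05,
                   cutoffs = list())
  cfg <- utils::modifyList(defaults, config)
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cfg$thickness <= 0) stop("thickness must be > 0 mm")
  cfg$n_per_grade <- stats::setNames(as.integer(unlist(cfg$n_per_grade)),
                                     c("G1", "G2", "G3"))
  structure(cfg, class = "pipeline_config")
}

log_stage <- function(...) message(sprintf("[pannenct %s] ", format(Sys.time(), "%H:%M:%S")), sprintf(...))

#' Pipeline stage: simulate a phantom cohort to disk
#'
#' @param config A [pipeline_config()] (or path/list coercible to one).
#' @return The cohort directory, invisibly.
#' @export
pipeline_simulate <- function(config = list()) {
  cfg <- pipeline_config(config)
  log_stage("simulate: %d patients -> %s (seed %d)",
            sum(cfg$n_per_grade), cfg$cohort_dir, cfg$master_seed)
  generate_cohort(n_per_grade = cfg$n_per_grade,
                  master_seed = cfg$master_seed, dir = cfg$cohort_dir)
  invisible(cfg$cohort_dir)
}

#' Pipeline stage: extract the cohort feature table
#'
#' Walks `cohort_dir`, reads each patient's phases, mask and ROI sidecar,
#' runs [extract_study_features()], and writes `features.csv` to `out_dir`.
#' Patients whose extraction fails are kept as flagged rows (`qc_fail`) with
#' NA features; grade labels and qualitative flags come from the cohort
#' manifest.
#'
#' @inheritParams pipeline_simulate
#' @return Path of the written CSV, invisibly.
#' @export
pipeline_extract <- function(config = list()) {
  cfg <- pipeline_config(config)
  man_path <- file.path(cfg$cohort_dir, "manifest.json")
  if (!file.exists(man_path))
    stop("no manifest.json in ", cfg$cohort_dir, "; not a cohort directory")
  manifest <- jsonlite::read_json(man_path)
  if (!length(manifest$patients)) stop("cohort manifest lists no patients")
  bcfg <- binning_config(n_bins = cfg$n_bins, range_mode = cfg$range_mode)
  rows <- lapply(manifest$patients, function(p) {
    pdir <- file.path(cfg$cohort_dir, p$patient_id)
    truth <- p$truth
    base <- cbind(data.frame(patient_id = p$patient_id, grade = p$grade,
                             size_mm = as.numeric(truth$size_mm)),
                  truth_flag_row(truth))
    feats <- tryCatch({
      vols <- list()
      for (ph in PHASES) {
        f <- file.path(pdir, paste0(ph, ".nii.gz"))
        if (file.exists(f)) vols[[ph]] <- read_volume(f, ph)
      }
      mask <- read_mask(file.path(pdir, "mask.nii.gz"))
      rois <- read_rois(file.path(pdir, "rois.json"))
      cbind(extract_study_features(vols, mask, rois, cfg = bcfg,
                                   thickness = cfg$thickness),
            data.frame(qc_fail = FALSE))
    }, error = function(e) {
      log_stage("extract: %s FAILED (%s)", p$patient_id, conditionMessage(e))
      cbind(empty_feature_row(), data.frame(qc_fail = TRUE))
    })
    cbind(base, feats)
  })
  df <- do.call(rbind, rows)[, cohort_columns()]
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(cfg$out_dir, "features.csv")
  write_cohort_table(df, out)
  log_stage("extract: %d/%d patients ok -> %s", sum(!df$qc_fail), nrow(df), out)
  invisible(out)
}

#' Pipeline stage: analyze the feature table
#'
#' Reads `out_dir/features.csv`, runs [grade_report()] and writes the report
#' bundle to `out_dir/report/`.
#'
#' @inheritParams pipeline_simulate
#' @return The [grade_report()], invisibly.
#' @export
pipeline_analyze <- function(config = list()) {
  cfg <- pipeline_config(config)
  path <- file.path(cfg$out_dir, "features.csv")
  if (!file.exists(path)) stop("no features.csv in ", cfg$out_dir,
                               "; run the extract stage first")
  cohort <- read_cohort_table(path)
  report <- grade_report(cohort, alpha = cfg$alpha, cutoffs = cfg$cutoffs)
  write_report_bundle(report, file.path(cfg$out_dir, "report"))
  log_stage("analyze: report written to %s", file.path(cfg$out_dir, "report"))
  invisible(report)
}
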