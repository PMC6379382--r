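# Volume containers, NIfTI round trips, slice resampling, cohort table I/O.

test_that("ct_volume and ct_mask enforce their invariants", {
  expect_error(ct_volume(array(0, c(4, 4)), c(1, 1, 1), phase = "portal"),
               "3D")
  expect_error(ct_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1),
                         phase = "portal"), "finite")
  expect_error(ct_volume(array(5000, c(2, 2, 2)), c(1, 1, 1),
                         phase = "portal"), "HU range")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 0, 1), phase = "portal"),
               "positive")
  expect_error(ct_volume(array(0, c(2, 2, 2)), c(1, 1, 1), phase = "bogus"))
  expect_error(ct_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
  m <- ct_mask(array(c(0, 2, 0, 0, 1, 0, 0, 0), c(2, 2, 2)), c(1, 1, 1))
  expect_identical(sum(m$voxels), 2L)  # nonzero = inside
})

test_that("NIfTI write/read round-trips volumes and masks exactly", {
  set.seed(11)
  for (ext in c(".nii", ".nii.gz")) {
    v <- ct_volume(array(rnorm(10 * 12 * 5, 60, 25), c(10, 12, 5)),
                   spacing = c(0.75, 0.5, 2.5), origin = c(-10, 3, 42),
                   phase = "portal")
    path <- withr::local_tempfile(fileext = ext)
    write_volume(v, path)
    v2 <- read_volume(path, "portal")
    expect_identical(v2$voxels, v$voxels)          # float64 storage: exact
    expect_equal(v2$spacing, v$spacing, tolerance = 1e-6)  # float32 header
    expect_equal(v2$origin, v$origin, tolerance = 1e-6)
    mask <- ct_mask(array(runif(10 * 12 * 5) > 0.5, c(10, 12, 5)),
                    spacing = v$spacing, origin = v$origin)
    mpath <- withr::local_tempfile(fileext = ext)
    write_mask(mask, mpath)
    expect_identical(read_mask(mpath)$voxels, mask$voxels)
  }
})

test_that("read_volume applies NIfTI intensity scaling and rejects bad input", {
  # file with scl_slope/inter written by nibabel-style headers is covered by
  # the cross-tool test; here: missing file and DICOM directory contracts
  expect_error(read_volume(file.path(tempdir(), "nope.nii"), "portal"),
               "not found")
  d <- withr::local_tempdir()
  expect_error(read_volume(d, "portal"), "DICOM")
  junk <- withr::local_tempfile(fileext = ".nii")
  writeBin(as.raw(rep(1, 400)), junk)
  expect_error(read_volume(junk, "portal"), "NIfTI")
})

test_that("our NIfTI dialect agrees with nibabel in both directions", {
  set.seed(21)
  v <- ct_volume(array(round(rnorm(8 * 8 * 4, 50, 20), 3), c(8, 8, 4)),
                 spacing = c(0.7, 0.7, 2.5), origin = c(1, 2, 3),
                 phase = "pancreatic")
  ours <- file.path(withr::local_tempdir(), "ours.nii.gz")
  theirs <- sub("ours", "theirs", ours)
  write_volume(v, ours)
  # nibabel reads our file; then writes an int16 + slope/intercept variant
  # (stored = HU + 1024, slope 1, inter -1024) that we must rescale on read
  script <- sprintf(paste0(
    "import nibabel as nib, numpy as np, sys\n",
    "img = nib.load('%s')\n",
    "d = np.asarray(img.dataobj)\n",
    "assert d.shape == (8, 8, 4)\n",
    "ref = np.loadtxt('%s').reshape(d.shape, order='F')\n",
    "assert np.allclose(d, ref, atol=1e-9), np.abs(d - ref).max()\n",
    "out = nib.Nifti1Image(np.rint(d + 1024).astype(np.int16), img.affine)\n",
    "out.header.set_slope_inter(1.0, -1024.0)\n",
    "nib.save(out, '%s')\n"), ours, paste0(ours, ".txt"), theirs)
  writeLines(sprintf("%.10f", as.vector(v$voxels)), paste0(ours, ".txt"))
  py <- file.path(dirname(ours), "check.py")
  writeLines(script, py)
  res <- system2("python", py, stdout = TRUE, stderr = TRUE)
  expect_identical(attr(res, "status"), NULL)
  v3 <- read_volume(theirs, "pancreatic")
  expect_equal(v3$voxels, round(v$voxels), tolerance = 1e-6)
})

test_that("resample_slices: identity, constancy and linear-ramp closed form", {
  set.seed(31)
  v5 <- ct_volume(array(rnorm(6 * 6 * 4, 0, 10), c(6, 6, 4)),
                  spacing = c(1, 1, 5), phase = "pancreatic")
  expect_identical(resample_slices(v5, 5)$voxels, v5$voxels)

  vc <- const_volume(100, dim = c(4, 4, 9), spacing = c(1, 1, 2.5))
  rc <- resample_slices(vc, 5)
  expect_true(all(rc$voxels == 100))
  expect_equal(rc$spacing[3], 5)

  # ramp: voxel value = its world z (mm); linear interp must be exact
  nz <- 17
  ramp <- ct_volume(
    aperm(array(rep((0:(nz - 1)) * 2.5, each = 1), c(nz, 3, 3)), c(2, 3, 1)),
    spacing = c(1, 1, 2.5), phase = "pancreatic")
  r <- resample_slices(ramp, 5)
  expect_equal(dim(r$voxels)[3], 9L)
  for (k in seq_len(9)) {
    expect_equal(unname(r$voxels[1, 1, k]), (k - 1) * 5, tolerance = 1e-6)
  }
  expect_error(resample_slices(ramp, -1), "positive")
  one <- const_volume(0, dim = c(3, 3, 1), spacing = c(1, 1, 2))
  expect_error(resample_slices(one, 5), "single-slice")
})

test_that("resample_slices preserves geometry and smooth-phantom means", {
  # smooth (band-limited) z profile: slow cosine, amplitude 50 HU
  nz <- 41
  z <- (0:(nz - 1)) * 1.25
  prof <- 50 + 50 * cos(2 * pi * z / 100)
  vox <- aperm(array(rep(prof, each = 16), c(nz, 4, 4)), c(2, 3, 1))
  v <- ct_volume(vox, spacing = c(1, 1, 1.25), origin = c(0, 0, 7),
                 phase = "pancreatic")
  r <- resample_slices(v, 5)
  expect_lt(abs(mean(r$voxels) - mean(v$voxels)), 0.5)
  # slice k center sits at origin_z + (k-1)*thickness
  expect_equal(r$origin[3], 7)
  expect_equal(r$spacing[3], 5)
})

test_that("cohort table round-trips losslessly", {
  df <- phantom_cohort_features(n_per_grade = c(2, 1, 1), master_seed = 5,
                                grid = phantom_grid(c(72, 72, 12)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_table(df, path)
  back <- read_cohort_table(path)
  expect_identical(nrow(back), 4L)
  expect_identical(back$patient_id, df$patient_id)
  expect_identical(back$margins, df$margins)
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      expect_equal(back[[col]], df[[col]], tolerance = 1e-12, info = col)
    } else {
      expect_identical(back[[col]], df[[col]], info = col)
    }
  }
  expect_error(write_cohort_table(df[0, ], path), "non-empty")
  dup <- rbind(df, df[1, ])
  expect_error(write_cohort_table(dup, path), "duplicate")
})
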