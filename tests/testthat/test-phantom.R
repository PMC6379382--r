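# Phantom generator: mixture-moment oracle, determinism, parameter recovery,
# cohort bookkeeping and the grade-separation mechanism.

test_that("mixture_moments: single Gaussian and Bernoulli limit", {
  m <- mixture_moments(1, 100, 10)
  expect_equal(unlist(m), c(mean = 100, variance = 100, skewness = 0,
                            kurtosis = 0))
  b <- mixture_moments(c(0.5, 0.5), c(0, 100), c(1e-9, 1e-9))
  expect_equal(b$mean, 50)
  expect_equal(b$variance, 2500, tolerance = 1e-9)
  expect_equal(b$kurtosis, -2, tolerance = 1e-6)
  expect_error(mixture_moments(c(0.6, 0.5), c(0, 1), c(1, 1)), "sum to 1")
  expect_error(mixture_moments(c(0.5, 0.5), c(0, 1), c(1, -1)), "nonnegative")
})

test_that("mixture_moments matches a Monte-Carlo oracle within 3 MC SEs", {
  w <- c(0.8, 0.2); mu <- c(120, 60); s <- c(10, 10)
  ana <- mixture_moments(w, mu, s)
  n <- 2e6
  set.seed(2024)
  comp <- sample.int(2, n, replace = TRUE, prob = w)
  x <- rnorm(n, mu[comp], s[comp])
  emp <- oracle_moments(x)
  expect_lt(abs(emp$mean - ana$mean), 3 * sqrt(ana$variance / n))
  expect_lt(abs(emp$variance - ana$variance),
            3 * ana$variance * sqrt(2 / n) * 3)  # generous var-of-var bound
  expect_lt(abs(emp$skewness - ana$skewness), 3 * sqrt(6 / n) * 5)
  expect_lt(abs(emp$kurtosis - ana$kurtosis), 3 * sqrt(24 / n) * 5)
})

test_that("generate_lesion is deterministic and honors the no-mixture limit", {
  prof <- grade_profile("G1", tumor_hu_art = c(120, 10),
                        tumor_hu_port = c(100, 10), necrosis_fraction = 0,
                        irregular_margin_prob = 0)
  a <- generate_lesion(prof, seed = 77, phases = "pancreatic")
  b <- generate_lesion(prof, seed = 77, phases = "pancreatic")
  expect_identical(a$volumes$pancreatic$voxels, b$volumes$pancreatic$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  # no necrosis -> single Gaussian -> excess kurtosis ~ 0
  tex <- texture_from_study(a$volumes$pancreatic, a$mask)
  n <- tex$n_voxels
  expect_gt(n, 1000)
  expect_lt(abs(tex$skewness), 3 * sqrt(6 / n))
  expect_lt(abs(tex$kurtosis), 3 * sqrt(24 / n))
  expect_equal(a$truth$necrosis_fraction_realized, 0)
})

test_that("moment standard errors reduce to the Gaussian closed forms", {
  se <- mixture_moment_ses(1, 0, 2, n = 1e4)
  expect_equal(se$mean, sqrt(4 / 1e4))
  expect_equal(se$variance, sqrt(2 * 16 / 1e4))       # (mu4 - mu2^2)/n = 2s^4/n
  expect_equal(se$skewness, sqrt(6 / 1e4))
  expect_equal(se$kurtosis, sqrt(24 / 1e4))
  # mixture SEs exceed the Gaussian formulas (heavy tails)
  sem <- mixture_moment_ses(c(0.88, 0.12), c(0, -70), c(12, 15), n = 1e4)
  expect_gt(sem$kurtosis, sqrt(24 / 1e4))
  expect_gt(sem$skewness, sqrt(6 / 1e4))
})

test_that("texture recovers the analytic mixture moments (manifest oracle)", {
  profs <- default_grade_profiles()
  for (seed in 1:6) {
    g <- c("G1", "G2", "G3")[(seed %% 3) + 1]
    les <- generate_lesion(profs[[g]], seed = 1000 + seed,
                           phases = "pancreatic")
    tex <- texture_from_study(les$volumes$pancreatic, les$mask)
    ana <- les$truth$moments
    cmp <- les$truth$components$pancreatic
    se <- mixture_moment_ses(cmp$weights, cmp$means, cmp$sds, tex$n_voxels)
    expect_lt(abs(tex$mean_value - ana$mean), 3 * se$mean)
    expect_lt(abs(tex$variance - ana$variance), 3 * se$variance)
    expect_lt(abs(tex$skewness - ana$skewness), 3 * se$skewness)
    expect_lt(abs(tex$kurtosis - ana$kurtosis), 3 * se$kurtosis)
  }
})

test_that("roi_quant recovers the true measurement set within 2 HU", {
  profs <- default_grade_profiles()
  for (seed in c(5, 6)) {
    for (g in c("G1", "G3")) {
      les <- generate_lesion(profs[[g]], seed = 400 + seed)
      feats <- extract_study_features(les$volumes, les$mask, les$rois)
      truth <- les$truth$measurements
      for (nm in names(truth)) {
        expect_lt(abs(feats[[nm]] - truth[[nm]]), 2,
                  label = sprintf("%s seed %d %s", g, seed, nm))
      }
    }
  }
})

test_that("generate_cohort writes the documented layout and manifest", {
  dir <- withr::local_tempdir()
  res <- generate_cohort(n_per_grade = c(2, 2, 2), master_seed = 9,
                         dir = dir, grid = phantom_grid(c(64, 64, 10)))
  ids <- sprintf("p%03d", 1:6)
  expect_true(all(dir.exists(file.path(dir, ids))))
  vols <- list.files(dir, pattern = "\\.nii\\.gz$", recursive = TRUE)
  expect_identical(length(grep("mask", vols)), 6L)
  expect_identical(length(vols), 24L)  # 3 phases + mask per patient
  expect_true(file.exists(file.path(dir, "manifest.json")))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = FALSE)
  expect_identical(length(man$patients), 6L)
  # manifest analytic moments match a mixture_moments recomputation exactly
  for (p in man$patients) {
    cmp <- p$truth$components$pancreatic
    re <- mixture_moments(unlist(cmp$weights), unlist(cmp$means),
                          unlist(cmp$sds))
    expect_equal(unlist(p$truth$moments), unlist(re), tolerance = 1e-12)
  }
  # same master seed -> identical manifest on disk
  dir2 <- withr::local_tempdir()
  generate_cohort(n_per_grade = c(2, 2, 2), master_seed = 9, dir = dir2,
                  grid = phantom_grid(c(64, 64, 10)))
  expect_identical(unname(tools::md5sum(file.path(dir, "manifest.json"))),
                   unname(tools::md5sum(file.path(dir2, "manifest.json"))))
  expect_identical(
    unname(tools::md5sum(file.path(dir, "p001", "pancreatic.nii.gz"))),
    unname(tools::md5sum(file.path(dir2, "p001", "pancreatic.nii.gz"))))
})

test_that("G3 lesions are more leptokurtic than G1 lesions (mechanism)", {
  profs <- default_grade_profiles()
  wins <- 0L
  n_rep <- 25L
  for (i in seq_len(n_rep)) {
    g1 <- generate_lesion(profs$G1, seed = 2 * i, phases = "pancreatic")
    g3 <- generate_lesion(profs$G3, seed = 2 * i + 1, phases = "pancreatic")
    k1 <- texture_from_study(g1$volumes$pancreatic, g1$mask)$kurtosis
    k3 <- texture_from_study(g3$volumes$pancreatic, g3$mask)$kurtosis
    if (k3 > k1) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})

test_that("grade_profile validates its parameters", {
  expect_error(grade_profile("G1", c(100, 10), c(90, 10),
                             necrosis_fraction = 1), "necrosis_fraction")
  expect_error(grade_profile("G1", c(100, 10), c(90, 10),
                             necrosis_hu_delta = 5), "negative")
  expect_error(grade_profile("G1", c(100, 0), c(90, 10)), "sd > 0")
  expect_error(grade_profile("G4", c(100, 10), c(90, 10)))
})
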