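# Grade statistics: chi-squared, Mann-Whitney, pooled t, ROC, report.

test_that("chi_square_test: independence, hand-computed and degenerate cases", {
  ind <- chi_square_test(rbind(c(10, 20), c(5, 10)))
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  diag <- chi_square_test(rbind(c(10, 0), c(0, 10)))
  expect_equal(diag$statistic, 20)
  expect_identical(diag$df, 1L)
  expect_equal(diag$p_value, stats::pchisq(20, 1, lower.tail = FALSE))
  expect_error(chi_square_test(rbind(c(1, 0), c(2, 0))), "all-zero")
  expect_error(chi_square_test(matrix(1:3, ncol = 1)), "2x2")
  # Yates on 2x2 shrinks the statistic
  y <- chi_square_test(rbind(c(8, 2), c(3, 7)), yates = TRUE)
  n <- chi_square_test(rbind(c(8, 2), c(3, 7)))
  expect_lt(y$statistic, n$statistic)
})

test_that("mann_whitney_test: textbook example and symmetry", {
  r <- mann_whitney_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  same <- mann_whitney_test(rep(c(1, 2, 3), 4), rep(c(1, 2, 3), 4))
  expect_equal(same$U, 12^2 / 2)
  expect_gte(same$p_value, 0.99)
  expect_error(mann_whitney_test(numeric(0), 1), "non-empty")
})

test_that("mann_whitney_test agrees with full enumeration for all n <= 4", {
  set.seed(55)
  for (na in 2:4) {
    for (nb in 2:4) {
      for (rep in 1:8) {
        a <- round(runif(na, 0, 10), 1)
        b <- round(runif(nb, 0, 10), 1)
        got <- mann_whitney_test(a, b, exact = TRUE)
        expect_equal(got$U, oracle_U(a, b),  # U of `a` counts a-over-b wins
                     tolerance = 1e-12)
        expect_equal(got$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-12)
      }
    }
  }
})

test_that("mann_whitney_test approximation is sane under ties and null", {
  set.seed(77)
  a <- sample(1:5, 30, replace = TRUE)
  b <- sample(1:5, 25, replace = TRUE)
  got <- mann_whitney_test(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("t_test_sizes matches the pooled t and handles degeneracy", {
  set.seed(3)
  a <- rnorm(12, 44, 25); b <- rnorm(9, 52, 25)
  got <- t_test_sizes(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  eq <- t_test_sizes(c(5, 5, 5), c(5, 5))
  expect_equal(eq$p_value, 1)
  ne <- t_test_sizes(c(5, 5, 5), c(7, 7))
  expect_equal(ne$p_value, 0)
  expect_true(ne$degenerate)
  expect_error(t_test_sizes(1, c(1, 2)), "at least 2")
})

test_that("roc_analysis: separation, chance line, tie handling, cutoffs", {
  sep <- roc_analysis(c(1, 2, 9, 10), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(sep$auc, 1)
  flat <- roc_analysis(rep(3, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(flat$auc, 0.5)
  tie <- roc_analysis(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(tie$auc, 0.875)
  # threshold convention: score >= cutoff is positive
  cut <- roc_analysis(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE),
                      cutoff = 3)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)
  lower <- roc_analysis(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                        direction = "lower_is_positive", cutoff = 2)
  expect_equal(lower$auc, 1)
  expect_equal(lower$sensitivity, 1)
  expect_equal(lower$specificity, 1)
  expect_error(roc_analysis(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("ROC curve invariants and AUC-U duality hold under fuzzing", {
  set.seed(808)
  for (i in 1:50) {
    n <- sample(6:40, 1)
    scores <- if (i %% 2) rnorm(n) else sample(1:5, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    r <- roc_analysis(scores, labels)
    expect_equal(r$curve$fpr[1], 0)
    expect_equal(r$curve$tpr[1], 0)
    expect_equal(utils::tail(r$curve$fpr, 1), 1)
    expect_equal(utils::tail(r$curve$tpr, 1), 1)
    expect_true(all(diff(r$curve$fpr) >= 0))
    expect_true(all(diff(r$curve$tpr) >= 0))
    expect_equal(r$auc, oracle_auc(scores, labels), tolerance = 1e-12)
    # duality with the U statistic of positives vs negatives
    U <- mann_whitney_test(scores[labels], scores[!labels])$U
    expect_equal(r$auc, U / (sum(labels) * sum(!labels)), tolerance = 1e-12)
  }
})

test_that("grade_report reproduces the published margin percentages", {
  # reconstructed 100-patient cohort from the printed margin counts:
  # sharp/irregular 30/1 (G1), 36/16 (G2), 8/9 (G3)
  cohort <- data.frame(
    patient_id = sprintf("p%03d", 1:100),
    grade = rep(c("G1", "G2", "G3"), times = c(31, 52, 17)),
    margins = c(rep("sharp", 30), "irregular",
                rep("sharp", 36), rep("irregular", 16),
                rep("sharp", 8), rep("irregular", 9)),
    kurtosis = c(rnorm(31, 0, 0.2), rnorm(52, 0.4, 0.4), rnorm(17, 2.8, 1))
  )
  rep <- grade_report(cohort)
  pct <- rep$qualitative$margins$percent
  expect_equal(pct["G1", "sharp"], 97)
  expect_equal(pct["G2", "sharp"], 69)
  expect_equal(pct["G3", "sharp"], 47)
  expect_equal(pct["G1", "irregular"], 3)
  expect_equal(pct["G2", "irregular"], 31)
  expect_equal(pct["G3", "irregular"], 53)
  expect_lt(rep$qualitative$margins$p_value, 0.05)
  # per-grade percentages sum to 100 +/- 1 (integer rounding)
  sums <- rowSums(pct)
  expect_true(all(abs(sums - 100) <= 1))
})

test_that("grade_report bookkeeping, ROC section and error contracts", {
  df <- phantom_cohort_features(n_per_grade = c(6, 6, 6), master_seed = 42,
                                grid = phantom_grid(c(72, 72, 12)))
  rep <- grade_report(df)
  expect_identical(nrow(rep$pairwise), (7L + 5L) * 3L)
  expect_identical(sort(unique(rep$pairwise$pair)),
                   sort(c("G1vG2", "G2vG3", "G1vG3")))
  expect_true(all(rep$pairwise$p_value >= 0 & rep$pairwise$p_value <= 1))
  expect_identical(nrow(rep$summary), (7L + 5L) * 3L)
  sig <- unique(rep$pairwise$feature[rep$pairwise$p_value < rep$alpha])
  expect_identical(sort(names(rep$roc)), sort(sig))
  for (r in rep$roc) expect_s3_class(r, "roc_result")
  expect_error(grade_report(df[df$grade == "G1", ]), "two grade")
  expect_error(grade_report(data.frame(x = 1)), "grade")
  # a tiny cohort with nothing significant: tables still come back
  tiny <- df[c(1, 7, 13), ]
  expect_warning(rep2 <- grade_report(tiny), "ROC skipped")
  expect_identical(length(rep2$roc), 0L)
})

test_that("report bundle writes its files", {
  df <- phantom_cohort_features(n_per_grade = c(3, 3, 3), master_seed = 8,
                                grid = phantom_grid(c(72, 72, 12)))
  rep <- suppressWarnings(grade_report(df))
  dir <- withr::local_tempdir()
  write_report_bundle(rep, dir)
  expect_true(all(file.exists(file.path(
    dir, c("qualitative.csv", "sizes.csv", "feature_summary.csv",
           "pairwise_tests.csv", "report.json")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(js$alpha, 0.05)
})
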