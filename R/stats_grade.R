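# Grade-group statistics: Pearson chi-squared for qualitative flags, pooled
# two-sample t for lesion sizes, pairwise Mann-Whitney U for ratio and texture
# features, and empirical ROC with cutoff evaluation for the significant ones.
# All tests are two-sided at alpha = 0.05 with no multiplicity correction,
# mirroring the clinical analysis this package reproduces.

GRADE_PAIRS <- list(G1vG2 = c("G1", "G2"), G2vG3 = c("G2", "G3"),
                    G1vG3 = c("G1", "G3"))

#' Round half away from zero
#'
#' Cohort tables report integer percentages rounded "half up" (0.5 -> 1),
#' not with R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pearson chi-squared test of independence
#'
#' `X2 = sum((O - E)^2 / E)` with expected counts from the row/column margins,
#' `df = (r - 1)(c - 1)`, upper-tail p. No continuity correction by default;
#' Yates' correction is available for 2x2 tables.
#'
#' @param contingency Count matrix (r x c, r, c >= 2). Any all-zero row or
#'   column is an error.
#' @param yates Apply Yates' continuity correction (2x2 only).
#' @return List `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(contingency, yates = FALSE) {
  tab <- as.matrix(contingency)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stop("contingency table must be at least 2x2")
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("contingency table must hold nonnegative finite counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0))
    stop("contingency table has an all-zero row or column")
  expected <- outer(rs, cs) / sum(tab)
  dev <- abs(tab - expected)
  if (yates) {
    if (!all(dim(tab) == c(2L, 2L)))
      stop("Yates' correction applies to 2x2 tables only")
    dev <- pmax(dev - 0.5, 0)
  }
  stat <- sum(dev^2 / expected)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Mann-Whitney U test (two-sided)
#'
#' Rank-based U with midranks for ties. The null distribution is evaluated
#' exactly by enumerating all `choose(n_a + n_b, n_a)` group labelings when
#' the combined sample size is at most `exact_limit` and there are no ties;
#' otherwise a normal approximation with tie correction and a 0.5 continuity
#' correction is used. Forcing `exact = TRUE` with ties runs the enumeration
#' as a permutation test on the midranks (still valid).
#'
#' @param a,b Non-empty numeric samples.
#' @param exact `TRUE`/`FALSE` to force the method, or `NULL` (default) for
#'   the automatic switch.
#' @param exact_limit Combined-size threshold for the automatic exact path
#'   (default 16).
#' @return List `U` (statistic of sample `a`), `p_value`, `method`, `n`.
#' @export
mann_whitney_test <- function(a, b, exact = NULL, exact_limit = 16L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (is.null(exact)) exact <- (n <= exact_limit) && !ties
  mu <- na * nb / 2
  if (exact) {
    cmb <- utils::combn(n, na)
    Us <- colSums(matrix(r[cmb], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    tt <- table(c(a, b))
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- max(0, (abs(U - mu) - 0.5)) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-z))
    }
    method <- "normal approximation with tie and continuity correction"
  }
  list(U = U, p_value = p, method = method, n = c(na, nb))
}

#' Pooled two-sample t test for lesion sizes
#'
#' Classical Student's t with pooled variance, two-sided. Degenerate inputs
#' are total: zero pooled variance with equal means gives `t = 0, p = 1`;
#' unequal means with zero variance gives `p = 0` with `degenerate = TRUE`.
#'
#' @param a,b Numeric samples (mm), each of length >= 2.
#' @return List `t`, `df`, `p_value`, `degenerate`.
#' @export
t_test_sizes <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 sizes")
  df <- na + nb - 2L
  s2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  if (s2 == 0) {
    if (dm == 0) return(list(t = 0, df = df, p_value = 1, degenerate = TRUE))
    return(list(t = sign(dm) * Inf, df = df, p_value = 0, degenerate = TRUE))
  }
  t <- dm / sqrt(s2 * (1 / na + 1 / nb))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       degenerate = FALSE)
}

#' Empirical ROC analysis
#'
#' Builds the empirical ROC over all distinct score thresholds. A case is
#' predicted positive when its score is `>=` the threshold (for
#' `higher_is_positive`; `<=` for `lower_is_positive`), so tied scores at the
#' threshold count as positive. AUC is the trapezoidal area, identical to
#' pair counting with ties counted 1/2. If `cutoff` is given, sensitivity and
#' specificity at that cutoff are reported under the same convention.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or coercible) vector: `TRUE` = positive class.
#' @param direction `"higher_is_positive"` or `"lower_is_positive"`.
#' @param cutoff Optional decision cutoff on the original score scale.
#' @return Object of class `roc_result`: `curve` (data.frame `fpr`, `tpr`,
#'   `threshold`), `auc`, `direction`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels,
                         direction = c("higher_is_positive",
                                       "lower_is_positive"),
                         cutoff = NULL) {
  direction <- match.arg(direction)
  scores <- as.numeric(scores)
  pos <- as.logical(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  if (anyNA(scores) || anyNA(pos)) stop("scores/labels must not contain NA")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present for ROC analysis")
  s <- if (direction == "lower_is_positive") -scores else scores
  th <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(s[pos] >= t), numeric(1)) / n_pos
  fpr <- vapply(th, function(t) sum(s[!pos] >= t), numeric(1)) / n_neg
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  sens <- spec <- NULL
  if (!is.null(cutoff)) {
    cs <- if (direction == "lower_is_positive") -cutoff else cutoff
    sens <- sum(s[pos] >= cs) / n_pos
    spec <- sum(s[!pos] < cs) / n_neg
  }
  structure(
    list(curve = data.frame(fpr = fpr, tpr = tpr,
                            threshold = c(Inf, th) *
                              if (direction == "lower_is_positive") -1 else 1),
         auc = auc, direction = direction, cutoff = cutoff,
         sensitivity = sens, specificity = spec,
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%s; %d pos / %d neg)\n",
              x$auc, x$direction, x$n_pos, x$n_neg))
  if (!is.null(x$cutoff))
    cat(sprintf("  cutoff %g: sensitivity %.2f, specificity %.2f\n",
                x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}

#' Default ROC direction per feature
#'
#' High-grade (G3) tumors show lower enhancement ratios and mean attenuation
#' but higher kurtosis, entropy and variance, so those are the directions in
#' which each feature is read as G3-positive. Skewness is read as
#' lower-is-positive: hypodense necrotic foci add a left tail to the
#' histogram.
#'
#' @return Named character vector mapping feature name to direction.
#' @export
default_direction_map <- function() {
  m <- c(stats::setNames(rep("lower_is_positive", length(RATIO_COLS)),
                         RATIO_COLS),
         mean_value = "lower_is_positive",
         variance = "higher_is_positive", skewness = "lower_is_positive",
         kurtosis = "higher_is_positive", entropy = "higher_is_positive")
  # delayed enhancement: portal minus arterial attenuation rises with grade
  m["tumor_permeability_ratio_2"] <- "higher_is_positive"
  m
}

#' Full grade-comparison report
#'
#' The cohort-level analysis: (i) per-grade contingency tables with integer
#' percentages (half-up rounding) and a chi-squared p for every qualitative
#' flag; (ii) pairwise pooled-t comparisons of lesion size; (iii) per-grade
#' min/max/mean/median summaries of every ratio and texture feature;
#' (iv) pairwise Mann-Whitney p-values for those features; and (v) ROC curves
#' (positive class G3 vs G1+G2) for every feature significant in any pairwise
#' comparison at level `alpha`. No multiple-testing correction is applied.
#'
#' @param cohort Data.frame with a `grade` column (`G1`/`G2`/`G3`) and any of
#'   the qualitative, ratio and texture columns of [cohort_columns()]. Rows
#'   with `qc_fail = TRUE` are dropped.
#' @param alpha Two-sided significance level (default 0.05).
#' @param direction_map Named direction vector, see [default_direction_map()].
#' @param cutoffs Optional named list of decision cutoffs per feature,
#'   forwarded to [roc_analysis()].
#' @return Object of class `grade_report` with elements `n_per_grade`,
#'   `qualitative`, `sizes`, `summary`, `pairwise`, `roc`, `alpha`.
#' @export
grade_report <- function(cohort, alpha = 0.05,
                         direction_map = default_direction_map(),
                         cutoffs = list()) {
  if (!is.data.frame(cohort) || !"grade" %in% names(cohort))
    stop("`cohort` must be a data.frame with a `grade` column")
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if ("qc_fail" %in% names(cohort))
    cohort <- cohort[!isTRUE_vec(cohort$qc_fail), , drop = FALSE]
  grades <- sort(unique(cohort$grade))
  if (length(grades) < 2L)
    stop("at least two grade groups are required, got: ",
         paste(grades, collapse = ", "))
  if (!all(grades %in% c("G1", "G2", "G3")))
    stop("grades must be G1/G2/G3")
  n_per_grade <- table(factor(cohort$grade, levels = grades))
  pairs <- Filter(function(p) all(p %in% grades), GRADE_PAIRS)

  # -- qualitative flags
  qual_cols <- intersect(QUAL_FLAG_COLS, names(cohort))
  qualitative <- lapply(qual_cols, function(col) {
    x <- cohort[[col]]
    lev <- if (is.logical(x)) c(FALSE, TRUE) else sort(unique(x))
    counts <- table(factor(cohort$grade, levels = grades),
                    factor(x, levels = lev))
    pct <- round_half_up(100 * prop.table(counts, margin = 1))
    test <- tryCatch(chi_square_test(unclass(counts)),
                     error = function(e) list(statistic = NA_real_,
                                              df = NA_integer_,
                                              p_value = NA_real_))
    list(feature = col, counts = counts, percent = pct,
         statistic = test$statistic, df = test$df, p_value = test$p_value)
  })
  names(qualitative) <- qual_cols

  # -- lesion sizes
  sizes <- NULL
  if ("size_mm" %in% names(cohort)) {
    sizes <- do.call(rbind, lapply(names(pairs), function(pn) {
      gg <- pairs[[pn]]
      res <- tryCatch(
        t_test_sizes(cohort$size_mm[cohort$grade == gg[1]],
                     cohort$size_mm[cohort$grade == gg[2]]),
        error = function(e) list(t = NA_real_, df = NA_integer_,
                                 p_value = NA_real_))
      data.frame(pair = pn, t = res$t, df = res$df, p_value = res$p_value)
    }))
  }

  # -- quantitative summaries and pairwise Mann-Whitney
  feat_cols <- intersect(c(RATIO_COLS, TEXTURE_COLS), names(cohort))
  # a feature is analyzable only if every grade contributes a finite value
  feat_cols <- Filter(function(col) {
    all(vapply(grades, function(g)
      any(is.finite(cohort[[col]][cohort$grade == g])), logical(1)))
  }, feat_cols)
  if (!length(feat_cols))
    stop("cohort has none of the ratio/texture feature columns populated")
  summary_tab <- do.call(rbind, lapply(feat_cols, function(col) {
    do.call(rbind, lapply(grades, function(g) {
      x <- cohort[[col]][cohort$grade == g]
      x <- x[is.finite(x)]
      data.frame(feature = col, grade = g, n = length(x),
                 min = min(x), max = max(x), mean = mean(x),
                 median = stats::median(x))
    }))
  }))
  pairwise <- do.call(rbind, lapply(feat_cols, function(col) {
    do.call(rbind, lapply(names(pairs), function(pn) {
      gg <- pairs[[pn]]
      x <- cohort[[col]][cohort$grade == gg[1]]
      y <- cohort[[col]][cohort$grade == gg[2]]
      x <- x[is.finite(x)]; y <- y[is.finite(y)]
      res <- mann_whitney_test(x, y)
      data.frame(feature = col, pair = pn, U = res$U, p_value = res$p_value,
                 n1 = res$n[1], n2 = res$n[2])
    }))
  }))

  # -- ROC for significant features, positive class G3
  roc <- list()
  sig_feats <- unique(pairwise$feature[pairwise$p_value < alpha])
  if (length(sig_feats) && "G3" %in% grades) {
    for (col in sig_feats) {
      ok <- is.finite(cohort[[col]])
      dirn <- direction_map[[col]]
      if (is.null(dirn) || is.na(dirn)) dirn <- "higher_is_positive"
      roc[[col]] <- roc_analysis(cohort[[col]][ok],
                                 cohort$grade[ok] == "G3",
                                 direction = dirn,
                                 cutoff = cutoffs[[col]])
    }
  } else if (length(sig_feats) == 0L) {
    warning("no feature significant at alpha = ", alpha, "; ROC skipped")
  }

  structure(
    list(n_per_grade = n_per_grade, qualitative = qualitative, sizes = sizes,
         summary = summary_tab, pairwise = pairwise, roc = roc,
         alpha = alpha),
    class = "grade_report"
  )
}

isTRUE_vec <- function(x) !is.na(x) & x

#' @export
print.grade_report <- function(x, ...) {
  cat("<grade_report>\n  patients per grade: ",
      paste(sprintf("%s=%d", names(x$n_per_grade), x$n_per_grade),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  qualitative flags tested: %d\n", length(x$qualitative)))
  cat(sprintf("  pairwise Mann-Whitney comparisons: %d\n", nrow(x$pairwise)))
  sig <- unique(x$pairwise$feature[x$pairwise$p_value < x$alpha])
  cat(sprintf("  significant features (alpha=%.2g): %s\n", x$alpha,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  for (f in names(x$roc))
    cat(sprintf("  ROC %s: AUC %.3f\n", f, x$roc[[f]]$auc))
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits CSV analogs of the cohort tables (qualitative percentages,
#' quantitative summaries, pairwise p-values, size comparisons) plus a JSON
#' summary including the ROC curves.
#'
#' @param report A [grade_report()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "grade_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  qual <- do.call(rbind, lapply(report$qualitative, function(q) {
    df <- as.data.frame(q$counts)
    names(df) <- c("grade", "level", "count")
    df$percent <- as.vector(q$percent)
    df$feature <- q$feature
    df$p_value <- q$p_value
    df
  }))
  if (!is.null(qual))
    utils::write.csv(qual, file.path(dir, "qualitative.csv"),
                     row.names = FALSE)
  if (!is.null(report$sizes))
    utils::write.csv(report$sizes, file.path(dir, "sizes.csv"),
                     row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "feature_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$pairwise, file.path(dir, "pairwise_tests.csv"),
                   row.names = FALSE)
  roc_json <- lapply(report$roc, function(r) {
    list(auc = r$auc, direction = r$direction, cutoff = r$cutoff,
         sensitivity = r$sensitivity, specificity = r$specificity,
         n_pos = r$n_pos, n_neg = r$n_neg, curve = r$curve)
  })
  jsonlite::write_json(
    list(alpha = report$alpha,
         n_per_grade = as.list(stats::setNames(as.integer(report$n_per_grade),
                                               names(report$n_per_grade))),
         roc = roc_json),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE, na = "null")
  invisible(dir)
}
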