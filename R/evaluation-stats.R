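#' ROC curve and AUROC
#'
#' Sweeps the unique predicted probabilities as thresholds (descending) to
#' build the ROC curve. The area is computed two ways — trapezoidal
#' integration of the curve and the Mann-Whitney pair-count statistic with
#' half credit for ties — and the two are asserted equal before returning.
#'
#' @param probs numeric scores (higher = more case-like).
#' @param labels binary outcome (1 = case).
#' @return list: `curve` (data.frame `threshold, fpr, tpr`, including the
#'   (0,0) and (1,1) endpoints) and `auroc`.
#' @export
compute_roc <- function(probs, labels) {
  labels <- as_binary(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  thr <- sort(unique(probs), decreasing = TRUE)
  tpr <- vapply(thr, function(th) sum(probs >= th & labels == 1L) / n1,
                numeric(1))
  fpr <- vapply(thr, function(th) sum(probs >= th & labels == 0L) / n0,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  if (curve$fpr[nrow(curve)] != 1 || curve$tpr[nrow(curve)] != 1)
    curve <- rbind(curve, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  trap <- sum(diff(curve$fpr) *
                (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  mw <- univariate_auroc(probs, labels)
  if (abs(trap - mw) > 1e-9)
    stop("internal ROC inconsistency: trapezoid and pair-count areas differ")
  list(curve = curve, auroc = mw)
}

# Placement values of the Mann-Whitney statistic: for each case, the
# fraction of controls it beats (ties half); and symmetrically per control.
delong_placements <- function(probs, labels) {
  cases <- probs[labels == 1L]
  controls <- probs[labels == 0L]
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls))
  r_case <- rank(cases)
  r_ctrl <- rank(controls)
  v10 <- (r_all[seq_len(m)] - r_case) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_ctrl) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated AUROCs
#'
#' Nonparametric comparison of the AUROCs of two models scored on the same
#' subjects, via the covariance of their Mann-Whitney placement values.
#' The variance of the AUROC difference is
#' `var_a + var_b - 2 cov`; `z` is the difference over its standard error
#' and the p-value is two-sided normal. 95% confidence intervals are
#' normal-approximation (`auc +/- 1.96 se`), clipped to \[0, 1\]. When the
#' difference has (numerically) zero variance the comparison is flagged
#' `degenerate`: identical score vectors give `z = 0, p = 1`, otherwise
#' `z` and `p` are `NA`.
#'
#' @param probs_a,probs_b scores of models A and B on the same subjects.
#' @param labels binary outcome (1 = case).
#' @return list of class `roc_comparison`: `auroc_a`, `auroc_b`,
#'   `delong_z`, `delong_p`, `cov` (2x2), `ci_a`, `ci_b`, `degenerate`.
#' @export
delong_compare <- function(probs_a, probs_b, labels) {
  labels <- as_binary(labels)
  if (length(probs_a) != length(probs_b) ||
      length(probs_a) != length(labels))
    stop("probs_a, probs_b, labels must have equal length")
  m <- sum(labels == 1L); n <- sum(labels == 0L)
  if (m == 0L || n == 0L) stop("both classes must be present")
  pa <- delong_placements(probs_a, labels)
  pb <- delong_placements(probs_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_d <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  diff_auc <- pa$auc - pb$auc
  degenerate <- !is.finite(var_d) || var_d < 1e-16
  if (degenerate) {
    z <- if (abs(diff_auc) < 1e-12) 0 else NA_real_
    p <- if (abs(diff_auc) < 1e-12) 1 else NA_real_
  } else {
    z <- diff_auc / sqrt(var_d)
    p <- 2 * stats::pnorm(-abs(z))
  }
  ci <- function(auc, v)
    pmin(1, pmax(0, auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(max(v, 0))))
  structure(list(
    auroc_a = pa$auc, auroc_b = pb$auc,
    delong_z = z, delong_p = p, cov = S,
    var_a = S[1, 1], var_b = S[2, 2],
    ci_a = ci(pa$auc, S[1, 1]), ci_b = ci(pb$auc, S[2, 2]),
    degenerate = degenerate
  ), class = "roc_comparison")
}

#' Variance of a single AUROC (DeLong)
#'
#' @param probs scores; @param labels binary outcome.
#' @return estimated variance of the AUROC.
#' @export
delong_variance <- function(probs, labels) {
  labels <- as_binary(labels)
  pl <- delong_placements(probs, labels)
  stats::var(pl$v10) / sum(labels == 1L) +
    stats::var(pl$v01) / sum(labels == 0L)
}

#' Confusion summary at a probability threshold
#'
#' Predicts the positive class when the probability strictly exceeds the
#' threshold (a probability of exactly 0.5 predicts the negative class at
#' the default threshold). Sensitivity is `tp / (tp + fn)`; specificity is
#' `tn / (tn + fp)`.
#'
#' @param probs probabilities in \[0, 1\].
#' @param labels binary outcome (1 = case).
#' @param threshold classification cut, default 0.5.
#' @return list of class `confusion_summary`: `tp, fp, tn, fn,
#'   sensitivity, specificity, threshold`.
#' @export
classify_and_summarize <- function(probs, labels, threshold = 0.5) {
  labels <- as_binary(labels)
  if (any(probs < 0 | probs > 1, na.rm = TRUE))
    stop("probs must lie in [0, 1]")
  pred <- probs > threshold
  tp <- sum(pred & labels == 1L); fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L); fp <- sum(pred & labels == 0L)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 threshold = threshold),
            class = "confusion_summary")
}

#' Exact McNemar test on paired correctness
#'
#' Given, for the same subjects, whether each of two classifiers was
#' correct, tests symmetry of the discordant pairs with the exact two-sided
#' binomial: `p = min(1, 2 P(Bin(b + c, 1/2) <= min(b, c)))` where `b` =
#' A correct, B wrong and `c` = A wrong, B correct; `p = 1` when there are
#' no discordant pairs.
#'
#' @param correct_a,correct_b logical vectors of equal length.
#' @return two-sided p-value.
#' @examples
#' mcnemar_exact(rep(TRUE, 5), rep(FALSE, 5))  # 2 * 0.5^5
#' @export
mcnemar_exact <- function(correct_a, correct_b) {
  if (length(correct_a) != length(correct_b)) stop("length mismatch")
  b <- sum(correct_a & !correct_b)
  cc <- sum(!correct_a & correct_b)
  n <- b + cc
  if (n == 0L) return(1)
  min(1, 2 * stats::pbinom(min(b, cc), n, 0.5))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Student's t with the pooled variance estimate, computed from group
#' means, SDs, and sizes (as printed in a cohort characteristics table).
#'
#' @param mean1,sd1,n1 group 1 summaries. @param mean2,sd2,n2 group 2.
#' @return list `t, df, p_value`.
#' @export
pooled_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

#' Chi-square test on a 2x2 events table
#'
#' Compares event counts `k1` of `n1` vs `k2` of `n2`; Yates continuity
#' correction by default.
#'
#' @param k1,n1,k2,n2 event and group counts.
#' @param correct apply the continuity correction (default `TRUE`).
#' @return list `statistic, p_value`.
#' @export
chisq_2x2 <- function(k1, n1, k2, n2, correct = TRUE) {
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Univariate cohort-characteristics table
#'
#' Compares AKI and no-AKI groups feature by feature: continuous features
#' with a pooled-variance two-sample t-test (group mean +/- SD reported),
#' categorical features with a Yates-corrected chi-square on the 2x2 table
#' (group n (%) reported, percentages rounded to integers). Total bypass
#' minutes are derived from each subject's timeline.
#'
#' @param cohort a `cohort`.
#' @param correct use the Yates continuity correction (default `TRUE`).
#' @return data.frame: `feature, test, summary_aki, summary_no_aki,
#'   p_value`.
#' @export
univariate_table <- function(cohort, correct = TRUE) {
  stopifnot(inherits(cohort, "cohort"))
  subj <- cohort$subjects
  aki <- vapply(subj, `[[`, logical(1), "aki")
  if (!any(aki) || all(aki)) stop("both outcome groups must be present")
  num <- function(f) vapply(subj, `[[`, numeric(1), f)
  cpb_min <- vapply(subj, function(s) {
    sum(vapply(s$timeline$cpb_runs, function(r) r[2] - r[1], numeric(1))) / 60
  }, numeric(1))
  cont <- list(age_y = num("age_y"), bmi = num("bmi"),
               baseline_creatinine_mg_dl = num("baseline_creatinine_mg_dl"),
               cpb_time_min = cpb_min)
  lg <- function(f) vapply(subj, `[[`, logical(1), f)
  proc <- vapply(subj, `[[`, character(1), "procedure_type")
  cat_ <- list(lvef_lt_35 = lg("lvef_lt_35"),
               insulin_dep_diabetes = lg("insulin_dep_diabetes"),
               female = vapply(subj, `[[`, character(1), "sex") == "female")
  for (lev in c("isolated_cabg", "single_valve", "valve_plus_cabg",
                "multi_valve", "other"))
    cat_[[paste0("proc_", lev)]] <- proc == lev

  rows <- list()
  for (nm in names(cont)) {
    x1 <- cont[[nm]][aki]; x0 <- cont[[nm]][!aki]
    tt <- stats::t.test(x1, x0, var.equal = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, test = "pooled_t",
      summary_aki = sprintf("%.2f ± %.2f", mean(x1), stats::sd(x1)),
      summary_no_aki = sprintf("%.2f ± %.2f", mean(x0), stats::sd(x0)),
      p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  for (nm in names(cat_)) {
    k1 <- sum(cat_[[nm]][aki]); n1 <- sum(aki)
    k0 <- sum(cat_[[nm]][!aki]); n0 <- sum(!aki)
    ct <- chisq_2x2(k1, n1, k0, n0, correct = correct)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, test = if (correct) "yates_chi2" else "chi2",
      summary_aki = sprintf("%d (%d)", k1, round(100 * k1 / n1)),
      summary_no_aki = sprintf("%d (%d)", k0, round(100 * k0 / n0)),
      p_value = ct$p_value, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Full paired-model comparison report
#'
#' Bundles the DeLong AUROC comparison, both confusion summaries at the
#' 0.5 threshold, and exact McNemar tests on sensitivity (within true
#' cases) and specificity (within true controls).
#'
#' @param loocv_a,loocv_b `loocv_result` objects for the same subjects
#'   (e.g. preoperative-only vs preoperative + PuO2).
#' @param threshold classification threshold, default 0.5.
#' @return list of class `model_comparison`.
#' @export
compare_models <- function(loocv_a, loocv_b, threshold = 0.5) {
  stopifnot(inherits(loocv_a, "loocv_result"), inherits(loocv_b, "loocv_result"))
  if (!identical(loocv_a$subject_id, loocv_b$subject_id) ||
      !identical(loocv_a$label, loocv_b$label))
    stop("the two results must cover the same subjects")
  ok <- !is.na(loocv_a$prob) & !is.na(loocv_b$prob)
  if (!all(ok)) {
    warning(sum(!ok), " subject(s) without a prediction (degenerate fold) ",
            "excluded from the comparison")
    loocv_a <- loocv_a[ok, ]
    loocv_b <- loocv_b[ok, ]
  }
  y <- loocv_a$label
  if (length(unique(y)) < 2L)
    stop("after excluding degenerate folds only one outcome class remains; ",
         "the cohort is too small or too imbalanced to compare models")
  roc <- delong_compare(loocv_a$prob, loocv_b$prob, y)
  conf_a <- classify_and_summarize(loocv_a$prob, y, threshold)
  conf_b <- classify_and_summarize(loocv_b$prob, y, threshold)
  pred_a <- loocv_a$prob > threshold
  pred_b <- loocv_b$prob > threshold
  pos <- y == 1L; neg <- y == 0L
  p_sens <- mcnemar_exact(pred_a[pos], pred_b[pos])
  p_spec <- mcnemar_exact(!pred_a[neg], !pred_b[neg])
  structure(list(
    model_a = attr(loocv_a, "model_tag"),
    model_b = attr(loocv_b, "model_tag"),
    roc = roc,
    confusion_a = conf_a,
    confusion_b = conf_b,
    mcnemar_p_sensitivity = p_sens,
    mcnemar_p_specificity = p_spec,
    threshold = threshold
  ), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Paired model comparison (%s vs %s)\n",
              x$model_a %||% "A", x$model_b %||% "B"))
  cat(sprintf("  AUROC: %.3f vs %.3f (DeLong z = %.3f, p = %.4g)\n",
              x$roc$auroc_a, x$roc$auroc_b, x$roc$delong_z, x$roc$delong_p))
  cat(sprintf("  Sensitivity: %.2f vs %.2f (McNemar p = %.4g)\n",
              x$confusion_a$sensitivity, x$confusion_b$sensitivity,
              x$mcnemar_p_sensitivity))
  cat(sprintf("  Specificity: %.2f vs %.2f (McNemar p = %.4g)\n",
              x$confusion_a$specificity, x$confusion_b$specificity,
              x$mcnemar_p_specificity))
  invisible(x)
}
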