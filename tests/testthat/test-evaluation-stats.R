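test_that("ROC examples and internal area cross-check", {
  r <- compute_roc(c(0.2, 0.8), c(0, 1))
  expect_equal(r$auroc, 1.0)
  expect_equal(compute_roc(rep(0.4, 6), c(0, 1, 0, 1, 0, 1))$auroc, 0.5)
  expect_equal(compute_roc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auroc, 0.75)
  expect_error(compute_roc(c(0.1, 0.2), c(1, 1)), "both classes")

  # curve endpoints and monotonicity
  set.seed(2)
  p <- runif(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  cur <- compute_roc(p, y)$curve
  expect_equal(cur$fpr[1], 0); expect_equal(cur$tpr[1], 0)
  expect_equal(cur$fpr[nrow(cur)], 1); expect_equal(cur$tpr[nrow(cur)], 1)
  expect_true(all(diff(cur$fpr) >= 0) && all(diff(cur$tpr) >= 0))
})

test_that("pair-count and trapezoid areas agree on many random instances", {
  set.seed(555)
  for (rep in 1:1000) {
    n <- sample(6:40, 1)
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) next
    # mix continuous and heavily tied score vectors
    p <- if (rep %% 3 == 0) sample(seq(0, 1, 0.1), n, replace = TRUE)
         else runif(n)
    r <- compute_roc(p, y)   # stops internally if the two areas differ
    expect_equal(r$auroc, auroc_pairs(p, y))
  }
})

test_that("DeLong agrees with pROC and behaves under degeneracy", {
  set.seed(42)
  n <- 60
  y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
  x <- rnorm(n) + y
  pa <- plogis(x + rnorm(n, 0, 0.5))
  pb <- plogis(0.3 * x + rnorm(n))
  cmp <- delong_compare(pa, pb, y)

  skip_if_not_installed("pROC")
  ref <- pROC::roc.test(pROC::roc(y, pa, quiet = TRUE),
                        pROC::roc(y, pb, quiet = TRUE),
                        method = "delong")
  expect_equal(unname(cmp$delong_z), unname(ref$statistic), tolerance = 1e-8)
  expect_equal(cmp$delong_p, ref$p.value, tolerance = 1e-8)
  expect_equal(cmp$auroc_a, as.numeric(pROC::auc(pROC::roc(y, pa, quiet = TRUE))),
               tolerance = 1e-10)

  # identical inputs: z = 0, p = 1
  same <- delong_compare(pa, pa, y)
  expect_equal(same$delong_z, 0)
  expect_equal(same$delong_p, 1)

  # antisymmetry
  rev <- delong_compare(pb, pa, y)
  expect_equal(rev$delong_z, -cmp$delong_z)
  expect_equal(rev$delong_p, cmp$delong_p)

  # covariance matrix is symmetric PSD
  expect_equal(cmp$cov[1, 2], cmp$cov[2, 1])
  expect_true(all(eigen(cmp$cov, only.values = TRUE)$values > -1e-12))
})

test_that("DeLong variance tracks the bootstrap and shrinks with separation", {
  set.seed(314)
  n <- 40
  y <- rep(c(0, 1), each = 20)
  p <- plogis(rnorm(n) + 1.2 * y)
  v_delong <- delong_variance(p, y)
  boot <- replicate(2000, {
    idx1 <- sample(which(y == 1), replace = TRUE)
    idx0 <- sample(which(y == 0), replace = TRUE)
    univariate_auroc(c(p[idx1], p[idx0]), c(y[idx1], y[idx0]))
  })
  expect_lt(abs(v_delong - var(boot)) / var(boot), 0.2)

  # variance vanishes as class separation approaches perfect: monotone
  # decrease along the sweep on a common noise realization
  vars <- sapply(c(1, 2, 3.5, 6), function(beta) {
    set.seed(10)
    delong_variance(plogis(rnorm(n) + beta * y), y)
  })
  expect_true(all(diff(vars) <= 0))   # zero once separation is perfect
  expect_lt(vars[4], vars[1])
  expect_lt(vars[4], 1e-6)
})

test_that("confusion summary uses a strict 0.5 threshold", {
  s <- classify_and_summarize(c(0.6, 0.4), c(1, 0))
  expect_equal(s$sensitivity, 1); expect_equal(s$specificity, 1)

  # exactly 0.5 predicts the negative class
  s2 <- classify_and_summarize(c(0.5, 0.5), c(1, 0))
  expect_equal(s2$tp, 0); expect_equal(s2$tn, 1)
  expect_equal(s2$sensitivity, 0); expect_equal(s2$specificity, 1)

  s3 <- classify_and_summarize(rep(0.9, 4), c(1, 1, 0, 0))
  expect_equal(s3$sensitivity, 1); expect_equal(s3$specificity, 0)
  expect_equal(s3$tp + s3$fn, 2); expect_equal(s3$tn + s3$fp, 2)
  expect_error(classify_and_summarize(c(1.2, 0.4), c(1, 0)), "\\[0, 1\\]")
})

test_that("exact McNemar matches closed forms and full enumeration", {
  expect_equal(mcnemar_exact(rep(TRUE, 5), rep(FALSE, 5)), 2 * 0.5^5)
  expect_equal(mcnemar_exact(logical(0), logical(0)), 1)
  expect_equal(mcnemar_exact(c(TRUE, TRUE), c(TRUE, TRUE)), 1)

  for (b in 0:6) for (cc in 0:6) {
    if (b + cc > 12 || b + cc == 0) next
    a_vec <- c(rep(TRUE, b), rep(FALSE, cc))
    b_vec <- c(rep(FALSE, b), rep(TRUE, cc))
    expect_equal(mcnemar_exact(a_vec, b_vec), mcnemar_enumerate(b, cc),
                 info = sprintf("b=%d c=%d", b, cc))
  }
  # b = c is always p = 1 under the capping convention
  for (k in 1:5)
    expect_equal(mcnemar_exact(c(rep(TRUE, k), rep(FALSE, k)),
                               c(rep(FALSE, k), rep(TRUE, k))), 1)
  expect_error(mcnemar_exact(TRUE, c(TRUE, FALSE)), "length")
})

test_that("summary-statistic tests reproduce printed cohort-table p-values", {
  # insulin-dependent diabetes: 14/46 vs 1/27 -> 0.015 with Yates
  dm <- chisq_2x2(14, 46, 1, 27, correct = TRUE)
  expect_equal(round(dm$p_value, 3), 0.015)
  expect_equal(dm$statistic, 5.90, tolerance = 0.01)

  # LVEF < 35%: 7/46 vs 2/27 -> 0.54 with Yates
  lvef <- chisq_2x2(7, 46, 2, 27, correct = TRUE)
  expect_equal(round(lvef$p_value, 2), 0.54)

  # without the correction the printed values are NOT reproduced
  expect_false(round(chisq_2x2(14, 46, 1, 27, correct = FALSE)$p_value, 3) ==
                 0.015)

  # bypass minutes: pooled t on printed summaries -> 0.62
  cpb <- pooled_t_summary(160.42, 55.28, 46, 167.74, 70.25, 27)
  expect_equal(round(cpb$p_value, 2), 0.62)
  # body mass index -> 0.05
  bmi <- pooled_t_summary(29.38, 5.89, 46, 26.57, 5.32, 27)
  expect_equal(round(bmi$p_value, 2), 0.05)
})

test_that("the univariate cohort table has both tests and sane percentages", {
  coh <- small_cohort(n = 40, seed = 50)
  tab <- univariate_table(coh)
  expect_true(all(c("pooled_t", "yates_chi2") %in% tab$test))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_true("cpb_time_min" %in% tab$feature)
  # percentages in the categorical summaries are integers
  cats <- tab[tab$test == "yates_chi2", ]
  pct <- as.integer(sub(".*\\((\\d+)\\)", "\\1", cats$summary_aki))
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("paired-model comparison bundles and serializes consistently", {
  set.seed(60)
  n <- 24
  y <- rep(c(0, 1), n / 2)
  mk <- function(p, tag) {
    out <- data.frame(subject_id = sprintf("M%02d", 1:n), label = y,
                      prob = p, fold = 1:n, degenerate = FALSE)
    attr(out, "model_tag") <- tag
    class(out) <- c("loocv_result", "data.frame")
    out
  }
  pa <- plogis(rnorm(n) + y)
  ra <- mk(pa, "preop_only")
  cmp_same <- compare_models(ra, mk(pa, "preop_plus_puo2"))
  expect_equal(cmp_same$roc$delong_z, 0)
  expect_equal(cmp_same$roc$delong_p, 1)
  expect_equal(cmp_same$mcnemar_p_sensitivity, 1)
  expect_equal(cmp_same$mcnemar_p_specificity, 1)

  rb <- mk(plogis(rnorm(n)), "preop_plus_puo2")
  cmp <- compare_models(ra, rb)
  expect_s3_class(cmp, "model_comparison")
  expect_output(print(cmp), "Paired model comparison")

  # report JSON round-trips the headline numbers losslessly
  tmp <- tempfile(fileext = ".json")
  rep_list <- list(auroc = list(a = cmp$roc$auroc_a, b = cmp$roc$auroc_b),
                   delong = list(z = cmp$roc$delong_z, p = cmp$roc$delong_p))
  write_report(rep_list, tmp)
  back <- read_report(tmp)
  expect_equal(back$auroc$a, cmp$roc$auroc_a)
  expect_equal(back$delong$z, cmp$roc$delong_z)

  bad <- mk(pa, "x"); bad$subject_id[1] <- "OTHER"
  expect_error(compare_models(ra, bad), "same subjects")

  # subjects without a prediction (degenerate folds) are excluded with a
  # warning, and the comparison proceeds on the rest
  na_a <- mk(pa, "preop_only"); na_a$prob[3] <- NA_real_
  expect_warning(cmp_na <- compare_models(na_a, rb), "degenerate fold")
  expect_equal(cmp_na$confusion_a$tp + cmp_na$confusion_a$fn +
                 cmp_na$confusion_a$tn + cmp_na$confusion_a$fp, n - 1L)
})
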