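test_that("period segmentation follows the surgical definitions", {
  tl <- make_timeline(surgery_end = 18000L,
                      runs = list(c(3600L, 7200L), c(9000L, 10800L)))
  w <- segment_periods(tl)
  expect_equal(w$period, c("pre_cpb", "cpb", "post_cpb"))
  expect_equal(w$start_s, c(0L, 3600L, 10800L))
  expect_equal(w$end_s, c(3600L, 10800L, 18000L))  # gap belongs to bypass

  w2 <- segment_periods(make_timeline(300L, list(c(100L, 200L))))
  expect_equal(w2$start_s, c(0L, 100L, 200L))
  expect_equal(w2$end_s, c(100L, 200L, 300L))      # contiguous cover

  expect_error(segment_periods(make_timeline(300L, list())), "no bypass runs")
  expect_error(segment_periods(
    make_timeline(400L, list(c(200L, 300L), c(100L, 150L)))),
    "non-overlapping and increasing")
})

test_that("low-flow rule converts the threshold with subject weight", {
  # 0.5 mL/kg/h at 80 kg is 0.667 mL/min; constant 0.5 mL/min is below it
  wf <- make_waveform(flow = 0.5)
  m <- compute_qc_mask(wf, weight_kg = 80)
  expect_true(all(!m$valid))
  expect_true(all(m$low_flow))

  # exactly at the cutoff: rate == 0.5 mL/kg/h, strict inequality keeps it
  wf_at <- make_waveform(flow = 0.5 * 80 / 60)
  m_at <- compute_qc_mask(wf_at, weight_kg = 80)
  expect_true(all(!m_at$low_flow))

  # comfortable flow: everything valid
  m_ok <- compute_qc_mask(make_waveform(flow = 5), weight_kg = 80)
  expect_true(all(m_ok$valid))
  expect_true(all(m_ok$reasons == ""))

  expect_error(compute_qc_mask(make_waveform(), weight_kg = 0), "positive")
  bad <- make_waveform(); bad$t_s[10] <- bad$t_s[9]
  expect_error(compute_qc_mask(bad, 80), "1 Hz grid")
})

test_that("retrograde, error-code, and stagnation rules mask what they should", {
  wf <- make_waveform(flow = 5)
  wf$flow_ml_min[50] <- -1
  qc0 <- qc_config(retrograde_guard_s = 0)
  m <- compute_qc_mask(wf, 80, qc0)
  expect_equal(m$t_s[m$retrograde], 49L)      # exactly that sample, guard 0
  expect_equal(sum(!m$valid), 1L)

  qc10 <- qc_config(retrograde_guard_s = 10)
  m10 <- compute_qc_mask(wf, 80, qc10)
  expect_equal(m10$t_s[m10$retrograde], 39:59)  # +/- 10 s guard

  wf_e <- make_waveform(flow = 5)
  wf_e$error_code[c(3, 200)] <- 2L
  m_e <- compute_qc_mask(wf_e, 80)
  expect_equal(m_e$t_s[m_e$error_code], c(2L, 199L))

  # a 61 s zero-flow run is stagnant (> 60 s strictly), a 60 s run is not
  wf_s <- make_waveform(t = 0:999, flow = 5)
  wf_s$flow_ml_min[100:160] <- 0    # 61 samples
  wf_s$flow_ml_min[500:559] <- 0    # 60 samples
  m_s <- compute_qc_mask(wf_s, 80, qc_config(stagnation_s = 60))
  expect_equal(m_s$t_s[m_s$stagnant], 99:159)
})

test_that("absent grid seconds are masked out_of_record", {
  wf <- make_waveform(t = c(0:99, 200:299), flow = 5)
  m <- compute_qc_mask(wf, 80, grid = c(0, 300))
  expect_equal(nrow(m), 300L)
  expect_equal(sum(m$out_of_record), 100L)
  expect_true(all(!m$valid[m$out_of_record]))
  expect_true(all(grepl("out_of_record", m$reasons[m$out_of_record])))
})

test_that("rules compose by union", {
  wf <- make_waveform(t = 0:499, flow = 5)
  wf$flow_ml_min[100] <- -2
  wf$error_code[300:305] <- 1L
  qc <- qc_config(retrograde_guard_s = 5)
  both <- compute_qc_mask(wf, 80, qc)

  only_r <- wf; only_r$error_code[] <- 0L
  only_e <- wf; only_e$flow_ml_min[100] <- 5
  m_r <- compute_qc_mask(only_r, 80, qc)
  m_e <- compute_qc_mask(only_e, 80, qc)
  expect_equal(!both$valid, (!m_r$valid) | (!m_e$valid))
})

test_that("relaxing thresholds never invalidates more samples", {
  set.seed(31)
  coh <- small_cohort(n = 3, seed = 31)
  for (s in coh$subjects) {
    strict <- qc_config(stagnation_s = 30, flow_threshold_ml_kg_h = 0.8)
    lax1 <- qc_config(stagnation_s = 120, flow_threshold_ml_kg_h = 0.8)
    lax2 <- qc_config(stagnation_s = 30, flow_threshold_ml_kg_h = 0.2)
    g <- c(s$timeline$surgery_start_s, s$timeline$surgery_end_s)
    v0 <- sum(compute_qc_mask(s$waveform, s$weight_kg, strict, g)$valid)
    expect_gte(sum(compute_qc_mask(s$waveform, s$weight_kg, lax1, g)$valid), v0)
    expect_gte(sum(compute_qc_mask(s$waveform, s$weight_kg, lax2, g)$valid), v0)
  }
})

test_that("the missingness rule drops strictly above 70% and keeps at 70%", {
  wf <- make_waveform(t = 0:299, flow = 5)
  windows <- segment_periods(make_timeline(300L, list(c(100L, 200L))))

  # 75 of the 100 pre-bypass samples invalid -> missing 0.75 -> dropped
  wf75 <- wf; wf75$error_code[1:75] <- 1L
  m75 <- compute_qc_mask(wf75, 80)
  v75 <- period_validity(m75, windows)
  expect_equal(v75$missing_fraction[1], 0.75)
  expect_false(v75$keep[1])

  # exactly 70 invalid -> missing 0.70 -> kept (strict "more than")
  wf70 <- wf; wf70$error_code[1:70] <- 1L
  v70 <- period_validity(compute_qc_mask(wf70, 80), windows)
  expect_equal(v70$missing_fraction[1], 0.70)
  expect_true(v70$keep[1])

  # fully clean -> missing 0, all kept
  v0 <- period_validity(compute_qc_mask(wf, 80), windows)
  expect_equal(v0$missing_fraction, rep(0, 3))
  expect_true(all(v0$keep))

  short <- compute_qc_mask(wf[wf$t_s < 250, ], 80)
  expect_error(period_validity(short, windows), "outside the mask range")
})

test_that("QC discards achieve recall 1.0 against injected artifact truth", {
  coh <- generate_cohort(cohort_config(
    n_subjects = 4, error_code_rate = 0.01, retrograde_rate = 3e-4,
    zero_flow_rate = 0, missing_period_prob = 0, rng_seed = 77))
  qc <- qc_config(retrograde_guard_s = 0)
  for (s in coh$subjects) {
    truth <- attr(s$waveform, "truth")
    m <- compute_qc_mask(s$waveform, s$weight_kg, qc,
                         grid = c(s$timeline$surgery_start_s,
                                  s$timeline$surgery_end_s))
    expect_true(all(truth$error %in% m$t_s[m$error_code]))
    expect_true(all(truth$retrograde %in% m$t_s[m$retrograde]))
  }
})

test_that("subject filtering excludes LVAD and incomplete-feature subjects", {
  coh <- small_cohort(n = 6, seed = 19)
  ft <- build_feature_table(coh)
  # force exactly one LVAD and one missing feature
  for (i in 1:6) coh$subjects[[i]]$lvad <- FALSE
  coh$subjects[[2]]$lvad <- TRUE
  ft2 <- ft
  ft2$puo2_mean_post_cpb[4] <- NA
  flt <- filter_cohort(coh, ft2)
  ids <- sapply(coh$subjects, `[[`, "subject_id")
  expect_true(ids[2] %in% flt$log$subject_id[flt$log$reason == "lvad"])
  expect_true(ids[4] %in%
                flt$log$subject_id[flt$log$reason == "missing_features"])
  expect_false(ids[2] %in% flt$included)
  expect_false(ids[4] %in% flt$included)
  expect_equal(length(flt$included) + nrow(flt$log), 6L)
})
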