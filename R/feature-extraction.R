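#' Distribution summaries of valid PuO2 samples
#'
#' Arithmetic mean, 25th percentile, median, and 75th percentile. Quantiles
#' interpolate linearly between order statistics (R type 7).
#'
#' @param valid_puo2 numeric vector of valid PuO2 samples (mmHg).
#' @return named numeric vector `mean, q25, median, q75`; all `NA` when the
#'   input is empty.
#' @examples
#' distribution_features(c(10, 20, 30, 40))
#' @export
distribution_features <- function(valid_puo2) {
  if (length(valid_puo2) == 0L || all(is.na(valid_puo2)))
    return(c(mean = NA_real_, q25 = NA_real_, median = NA_real_,
             q75 = NA_real_))
  q <- stats::quantile(valid_puo2, c(0.25, 0.5, 0.75), names = FALSE,
                       type = 7, na.rm = TRUE)
  c(mean = mean(valid_puo2, na.rm = TRUE), q25 = q[1], median = q[2],
    q75 = q[3])
}

#' Time spent below a PuO2 threshold
#'
#' Counts valid 1 Hz samples strictly below the threshold and converts to
#' minutes. Exposure is a sum over samples, so masked gaps contribute
#' nothing and sample order is irrelevant.
#'
#' @param valid_samples numeric vector of valid 1 Hz PuO2 samples (mmHg).
#' @param threshold threshold in mmHg (> 0).
#' @return minutes below threshold.
#' @examples
#' time_below(c(30, 40, 30, 36, 20), 35)  # 3 samples -> 0.05 min
#' @export
time_below <- function(valid_samples, threshold) {
  stopifnot(threshold > 0)
  sum(valid_samples < threshold, na.rm = TRUE) / 60
}

#' Area below a PuO2 threshold
#'
#' Cumulative depth of exposure: the sum of `threshold - PuO2` over valid
#' samples below the threshold, in mmHg-minutes.
#'
#' @inheritParams time_below
#' @return area in mmHg-min; bounded by `threshold * time_below(...)`.
#' @examples
#' area_below(c(30, 40, 30, 36, 20), 35)  # 25/60 mmHg-min
#' @export
area_below <- function(valid_samples, threshold) {
  stopifnot(threshold > 0)
  sum(pmax(0, threshold - valid_samples), na.rm = TRUE) / 60
}

#' Build the candidate feature table
#'
#' One row per subject: preoperative demographics (procedure type one-hot
#' encoded against an `isolated_cabg` reference, sex encoded female = 1)
#' plus, for each kept surgical period, PuO2 distribution summaries and, for
#' each period-threshold pair, time and area below the threshold. Features
#' of a dropped period (missingness rule) are `NA`. Column order is
#' deterministic.
#'
#' @param cohort a `cohort`.
#' @param qc a [qc_config()] used to mask the waveforms.
#' @param thresholds PuO2 threshold grid in mmHg (non-empty).
#' @param normalize_exposure divide exposure features by the period's valid
#'   minutes (default `FALSE`: the working hypothesis is cumulative, not
#'   fractional, exposure).
#' @return data.frame with `subject_id`, `aki`, and feature columns;
#'   attribute `feature_meta` is a data.frame
#'   `feature, source, period, threshold`.
#' @export
build_feature_table <- function(cohort, qc = qc_config(),
                                thresholds = c(15, 25, 35),
                                normalize_exposure = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(thresholds) == 0L) stop("threshold list must be non-empty")
  periods <- c("pre_cpb", "cpb", "post_cpb")
  stats_nm <- c("mean", "q25", "median", "q75")
  dist_cols <- as.vector(t(outer(periods, stats_nm, function(p, s)
    paste0("puo2_", s, "_", p))))
  expo_cols <- unlist(lapply(periods, function(p)
    unlist(lapply(thresholds, function(th)
      paste0("puo2_", c("time", "area"), "_below_", format(th), "_", p)))))
  preop_cols <- c("age_y", "sex_female", "bmi", "baseline_creatinine_mg_dl",
                  "insulin_dep_diabetes", "lvef_lt_35",
                  "proc_single_valve", "proc_valve_plus_cabg",
                  "proc_multi_valve", "proc_other")

  rows <- lapply(cohort$subjects, function(s) {
    windows <- segment_periods(s$timeline)
    mask <- compute_qc_mask(s$waveform, s$weight_kg, qc,
                            grid = c(s$timeline$surgery_start_s,
                                     s$timeline$surgery_end_s))
    windows <- period_validity(mask, windows, qc$max_missing_fraction)
    puo2_by_period <- lapply(seq_len(nrow(windows)), function(i) {
      if (!windows$keep[i]) return(NULL)
      sel <- mask$t_s >= windows$start_s[i] & mask$t_s < windows$end_s[i] &
        mask$valid
      s$waveform$puo2_mmHg[match(mask$t_s[sel], s$waveform$t_s)]
    })
    names(puo2_by_period) <- windows$period

    vals <- c(
      age_y = s$age_y,
      sex_female = as.numeric(s$sex == "female"),
      bmi = s$bmi,
      baseline_creatinine_mg_dl = s$baseline_creatinine_mg_dl,
      insulin_dep_diabetes = as.numeric(s$insulin_dep_diabetes),
      lvef_lt_35 = as.numeric(s$lvef_lt_35),
      proc_single_valve = as.numeric(s$procedure_type == "single_valve"),
      proc_valve_plus_cabg = as.numeric(s$procedure_type == "valve_plus_cabg"),
      proc_multi_valve = as.numeric(s$procedure_type == "multi_valve"),
      proc_other = as.numeric(s$procedure_type == "other")
    )
    for (p in periods) {
      x <- puo2_by_period[[p]]
      d <- if (is.null(x)) rep(NA_real_, 4) else distribution_features(x)
      vals[paste0("puo2_", stats_nm, "_", p)] <- unname(d)
      denom <- if (normalize_exposure && !is.null(x)) length(x) / 60 else 1
      for (th in thresholds) {
        tb <- if (is.null(x) || length(x) == 0L) NA_real_
              else time_below(x, th) / denom
        ab <- if (is.null(x) || length(x) == 0L) NA_real_
              else area_below(x, th) / denom
        vals[paste0("puo2_time_below_", format(th), "_", p)] <- tb
        vals[paste0("puo2_area_below_", format(th), "_", p)] <- ab
      }
    }
    vals
  })
  mat <- do.call(rbind, rows)
  all_cols <- c(preop_cols, dist_cols, expo_cols)
  out <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, character(1), "subject_id"),
    aki = vapply(cohort$subjects, `[[`, logical(1), "aki"),
    mat[, all_cols, drop = FALSE],
    stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(out) <- NULL
  meta <- data.frame(
    feature = all_cols,
    source = c(rep("preop", length(preop_cols)),
               rep("puo2", length(dist_cols) + length(expo_cols))),
    period = c(rep(NA_character_, length(preop_cols)),
               rep(periods, each = length(stats_nm)),
               rep(periods, each = 2L * length(thresholds))),
    threshold = c(rep(NA_real_, length(preop_cols) + length(dist_cols)),
                  rep(rep(thresholds, each = 2L), times = length(periods))),
    stringsAsFactors = FALSE
  )
  attr(out, "feature_meta") <- meta
  out
}

#' Names of preoperative / PuO2 feature columns
#'
#' @param feature_matrix output of [build_feature_table()].
#' @return character vector of column names.
#' @export
preop_feature_names <- function(feature_matrix) {
  meta <- attr(feature_matrix, "feature_meta")
  meta$feature[meta$source == "preop"]
}

#' @rdname preop_feature_names
#' @export
puo2_feature_names <- function(feature_matrix) {
  meta <- attr(feature_matrix, "feature_meta")
  meta$feature[meta$source == "puo2"]
}
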