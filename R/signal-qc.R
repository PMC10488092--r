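#' Segment a surgical record into analysis periods
#'
#' Splits `[surgery_start, surgery_end)` into three half-open intervals:
#' pre-bypass `[surgery_start, first run start)`, bypass
#' `[first run start, last run end)` (inter-run gaps included), and
#' post-bypass `[last run end, surgery_end)`.
#'
#' @param timeline a `surgical_timeline`.
#' @return data.frame of class `period_windows` with columns
#'   `period` (`pre_cpb`, `cpb`, `post_cpb`), `start_s`, `end_s`.
#' @examples
#' tl <- structure(list(surgery_start_s = 0L, surgery_end_s = 18000L,
#'                      cpb_runs = list(c(3600L, 7200L), c(9000L, 10800L))),
#'                 class = "surgical_timeline")
#' segment_periods(tl)
#' @export
segment_periods <- function(timeline) {
  stopifnot(inherits(timeline, "surgical_timeline"))
  runs <- timeline$cpb_runs
  if (length(runs) == 0L) stop("timeline has no bypass runs")
  starts <- vapply(runs, `[`, numeric(1), 1)
  ends <- vapply(runs, `[`, numeric(1), 2)
  if (any(ends <= starts) || is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] < ends[-length(ends)]))
    stop("bypass runs must be non-overlapping and increasing")
  if (timeline$surgery_start_s >= starts[1] ||
      ends[length(ends)] >= timeline$surgery_end_s)
    stop("bypass runs must lie strictly inside the surgery window")
  out <- data.frame(
    period = c("pre_cpb", "cpb", "post_cpb"),
    start_s = as.integer(c(timeline$surgery_start_s, starts[1],
                           ends[length(ends)])),
    end_s = as.integer(c(starts[1], ends[length(ends)],
                         timeline$surgery_end_s)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("period_windows", "data.frame")
  out
}

#' Compute the per-sample artifact-discard mask
#'
#' Applies the discard rules to a 1 Hz waveform record. A sample is invalid
#' if any rule flags it (rules compose by union):
#' \describe{
#'   \item{error_code}{the flow-sensor error code is nonzero.}
#'   \item{retrograde}{urine flow is negative at the sample or within
#'     `retrograde_guard_s` seconds of a negative sample.}
#'   \item{stagnant}{the sample lies in a maximal run of near-zero flow
#'     (|flow| < `zero_flow_eps`) lasting strictly longer than
#'     `stagnation_s`.}
#'   \item{low_flow}{the trailing `flow_window_s`-second mean flow,
#'     converted to mL/kg/h as `flow_ml_min * 60 / weight_kg`, is strictly
#'     below `flow_threshold_ml_kg_h`.}
#'   \item{out_of_record}{the grid second is absent from the record
#'     (device disconnected).}
#' }
#'
#' @param series waveform data.frame (`t_s, puo2_mmHg, flow_ml_min,
#'   temp_c, error_code`); timestamps strictly increasing integers, gaps
#'   allowed.
#' @param weight_kg subject weight (> 0) for the mL/kg/h conversion.
#' @param qc a [qc_config()].
#' @param grid optional `c(start_s, end_s)` half-open analysis grid;
#'   defaults to the span of the record. Grid seconds not present in
#'   `series` are marked `out_of_record`.
#' @return data.frame of class `qc_mask`: `t_s`, `valid`, one logical
#'   column per reason, and `reasons` (`;`-joined labels, empty when valid).
#' @export
compute_qc_mask <- function(series, weight_kg, qc = qc_config(), grid = NULL) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || weight_kg <= 0)
    stop("weight_kg must be a positive scalar")
  need <- c("t_s", "puo2_mmHg", "flow_ml_min", "error_code")
  if (!all(need %in% names(series)))
    stop("series lacks required columns: ",
         paste(setdiff(need, names(series)), collapse = ", "))
  ts <- series$t_s
  if (length(ts) && (any(diff(ts) < 1) || any(ts != round(ts))))
    stop("series must be on a strictly increasing integer 1 Hz grid")
  if (is.null(grid)) grid <- c(min(ts), max(ts) + 1L)
  t_grid <- seq.int(grid[1], grid[2] - 1L)
  n <- length(t_grid)

  pos <- match(t_grid, ts)
  present <- !is.na(pos)
  flow <- rep(NA_real_, n)
  flow[present] <- series$flow_ml_min[pos[present]]
  ecode <- rep(NA_integer_, n)
  ecode[present] <- series$error_code[pos[present]]

  r_error <- present & ecode != 0L
  r_retro <- dilate_logical(present & !is.na(flow) & flow < 0,
                            qc$retrograde_guard_s)
  r_retro <- r_retro & present

  # stagnant: maximal near-zero-flow runs strictly longer than the limit;
  # absent samples break a run
  near0 <- present & !is.na(flow) & abs(flow) < qc$zero_flow_eps
  r_stag <- logical(n)
  rl <- rle(near0)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  long <- which(rl$values & rl$lengths > qc$stagnation_s)
  for (k in long) r_stag[starts[k]:ends[k]] <- TRUE

  rate <- trailing_mean(flow, qc$flow_window_s) * 60 / weight_kg
  # strictly below the threshold, with a relative tolerance so a rate equal
  # to the threshold up to accumulation rounding is not discarded
  tol <- 1e-9 * max(qc$flow_threshold_ml_kg_h, 1)
  r_low <- present & !is.na(rate) & rate < qc$flow_threshold_ml_kg_h - tol

  reasons <- cbind(error_code = r_error, retrograde = r_retro,
                   stagnant = r_stag, low_flow = r_low,
                   out_of_record = !present)
  valid <- !apply(reasons, 1, any)
  lbl <- colnames(reasons)
  reason_str <- apply(reasons, 1, function(r)
    paste(lbl[r], collapse = ";"))
  out <- data.frame(t_s = t_grid, valid = valid, reasons, reason_str,
                    stringsAsFactors = FALSE)
  names(out)[ncol(out)] <- "reasons"
  class(out) <- c("qc_mask", "data.frame")
  out
}

#' Apply the period missingness rule
#'
#' A period's missing fraction is `1 - valid / length` over its grid
#' seconds, counting both discarded and absent samples as missing. The
#' period is dropped when the fraction strictly exceeds
#' `max_missing` ("more than 70\%" by default).
#'
#' @param mask a `qc_mask` covering all window seconds.
#' @param windows a `period_windows` from [segment_periods()].
#' @param max_missing drop threshold, default 0.70.
#' @return `windows` with `missing_fraction` and `keep` columns added.
#' @export
period_validity <- function(mask, windows, max_missing = 0.70) {
  stopifnot(inherits(mask, "qc_mask"), inherits(windows, "period_windows"))
  if (min(windows$start_s) < min(mask$t_s) ||
      max(windows$end_s) > max(mask$t_s) + 1L)
    stop("period windows extend outside the mask range")
  windows$missing_fraction <- vapply(seq_len(nrow(windows)), function(i) {
    sel <- mask$t_s >= windows$start_s[i] & mask$t_s < windows$end_s[i]
    1 - sum(mask$valid[sel]) / sum(sel)
  }, numeric(1))
  windows$keep <- !(windows$missing_fraction > max_missing)
  windows
}

#' Apply subject-level exclusions
#'
#' Excludes ventricular-assist-device recipients and any subject with one or
#' more missing candidate features (e.g. because a whole period was dropped
#' by the missingness rule).
#'
#' @param cohort a `cohort`.
#' @param feature_matrix data.frame from [build_feature_table()] with a
#'   `subject_id` column; `NA` marks a missing feature.
#' @return list with `included` (character subject ids) and `log`
#'   (data.frame `subject_id`, `reason` in `{lvad, missing_features}`).
#' @export
filter_cohort <- function(cohort, feature_matrix) {
  stopifnot(inherits(cohort, "cohort"), "subject_id" %in% names(feature_matrix))
  ids <- vapply(cohort$subjects, `[[`, character(1), "subject_id")
  lvad <- vapply(cohort$subjects, `[[`, logical(1), "lvad")
  fm <- feature_matrix[match(ids, feature_matrix$subject_id), , drop = FALSE]
  vals <- fm[, setdiff(names(fm), "subject_id"), drop = FALSE]
  has_missing <- apply(vals, 1, function(r) any(is.na(r)))
  log <- data.frame(subject_id = character(0), reason = character(0),
                    stringsAsFactors = FALSE)
  if (any(lvad))
    log <- rbind(log, data.frame(subject_id = ids[lvad], reason = "lvad"))
  mf <- !lvad & has_missing
  if (any(mf))
    log <- rbind(log, data.frame(subject_id = ids[mf],
                                 reason = "missing_features"))
  list(included = ids[!lvad & !has_missing], log = log)
}
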