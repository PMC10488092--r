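#' Generate a synthetic cardiac-surgery cohort
#'
#' Draws subjects with group-conditional demographics (AKI vs no-AKI), a
#' surgical timeline (surgery start/end and 1-3 cardiopulmonary-bypass runs),
#' and a 1 Hz waveform record carrying urine oximetry (PuO2), urine flow,
#' temperature, and flow-sensor error codes. AKI subjects receive a
#' configurable post-bypass PuO2 deficit (`delta_mmHg`), the generator's
#' ground-truth effect. Artifacts (retrograde-flow blips, zero-flow episodes,
#' error codes, absent record chunks) are injected at configured rates and
#' recorded as hidden truth masks so downstream QC can be scored against
#' them.
#'
#' @param config a [cohort_config()].
#' @return object of class `cohort`: list with `subjects` (list of
#'   `subject_record`) and `config`. Each `subject_record` holds the
#'   demographic fields, the AKI label, `timeline` (class
#'   `surgical_timeline`), and `waveform` (data.frame
#'   `t_s, puo2_mmHg, flow_ml_min, temp_c, error_code` with a `truth`
#'   attribute of injected-artifact masks).
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 4, rng_seed = 7))
#' sapply(coh$subjects, function(s) s$aki)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$rng_seed)
  subject_seeds <- sapply(seq_len(config$n_subjects), function(i)
    derive_seed(config$rng_seed, i))
  aki <- stats::rbinom(config$n_subjects, 1L, config$aki_prevalence) == 1L
  subjects <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_seeds[i])
    subjects[[i]] <- generate_subject(sprintf("S%03d", i), aki[i], config)
  }
  structure(list(subjects = subjects, config = config), class = "cohort")
}

generate_subject <- function(id, aki, config) {
  grp <- if (aki) config$demographics$aki else config$demographics$no_aki
  sex <- if (stats::runif(1) < grp$p_female) "female" else "male"
  # Table-style summaries report BMI, not weight; weight comes from BMI and a
  # sex-specific height so the mL/kg/h discard rule has a kg denominator.
  height_cm <- if (sex == "female") rnorm_trunc(1, 162, 7, 140, 190)
               else rnorm_trunc(1, 176, 7, 150, 205)
  bmi <- rnorm_trunc(1, grp$bmi["mean"], grp$bmi["sd"], 15, 55)
  subject <- structure(list(
    subject_id = id,
    age_y = rnorm_trunc(1, grp$age["mean"], grp$age["sd"], 18, 95),
    sex = sex,
    bmi = unname(bmi),
    weight_kg = unname(bmi * (height_cm / 100)^2),
    baseline_creatinine_mg_dl =
      rnorm_trunc(1, grp$creatinine["mean"], grp$creatinine["sd"], 0.3, 4),
    insulin_dep_diabetes = stats::runif(1) < grp$p_diabetes,
    lvef_lt_35 = stats::runif(1) < grp$p_lvef_lt_35,
    procedure_type = sample(names(grp$procedure), 1, prob = grp$procedure),
    lvad = stats::runif(1) < config$lvad_prob,
    aki = aki,
    timeline = NULL,
    waveform = NULL
  ), class = "subject_record")
  subject$timeline <- generate_timeline(config,
                                        group = if (aki) "aki" else "no_aki")
  subject$waveform <- generate_waveform(subject, config)
  subject
}

#' Generate a surgical timeline
#'
#' Surgery runs from second 0; the bypass phase holds 1-3 non-overlapping
#' runs whose total on-pump time is drawn near the group's mean bypass
#' duration. Uses the current RNG stream; seed it for reproducibility.
#'
#' @param config a [cohort_config()].
#' @param group `"aki"` or `"no_aki"`; selects the bypass-duration
#'   parameters.
#' @return object of class `surgical_timeline`: list with `surgery_start_s`,
#'   `surgery_end_s`, and `cpb_runs` (list of `c(start_s, end_s)`).
#' @export
generate_timeline <- function(config, group = c("aki", "no_aki")) {
  group <- match.arg(group)
  grp <- config$demographics[[group]]
  pre_s <- round(60 * rnorm_trunc(1, 75, 15, 30, 180))
  cpb_total_s <- round(60 * rnorm_trunc(1, grp$cpb_min["mean"],
                                        grp$cpb_min["sd"], 30, 420))
  post_s <- round(60 * rnorm_trunc(1, 90, 20, 30, 240))
  n_runs <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
  # split total on-pump time over runs; gaps of 5-20 min between runs
  w <- stats::runif(n_runs, 0.5, 1); w <- w / sum(w)
  run_len <- pmax(300, round(cpb_total_s * w))
  gaps <- if (n_runs > 1) round(60 * stats::runif(n_runs - 1, 5, 20)) else integer(0)
  starts <- pre_s + cumsum(c(0, run_len[-n_runs] + gaps))
  ends <- starts + run_len
  structure(list(
    surgery_start_s = 0L,
    surgery_end_s = as.integer(ends[n_runs] + post_s),
    cpb_runs = lapply(seq_len(n_runs), function(k)
      c(as.integer(starts[k]), as.integer(ends[k])))
  ), class = "surgical_timeline")
}

#' Generate a 1 Hz waveform record for one subject
#'
#' The PuO2 channel is a discretized Ornstein-Uhlenbeck (mean-reverting
#' AR(1)) process whose target mean shifts by surgical period, ramping over
#' five minutes at each transition; AKI subjects' post-bypass target is
#' lowered by `delta_mmHg`. Flow is log-normal around the configured urine
#' output target with slow autocorrelated variation, so the subject's
#' trailing flow rate in mL/kg/h occasionally dips below the 0.5 discard
#' threshold. Artifacts are injected and recorded in the `truth` attribute:
#' `error` (nonzero error codes), `retrograde` (negative-flow blips),
#' `zero_flow` (stagnation episodes), each a vector of affected `t_s`.
#' Uses the current RNG stream.
#'
#' @param subject a `subject_record` with `timeline` and `weight_kg` set.
#' @param config a [cohort_config()].
#' @return data.frame `t_s, puo2_mmHg, flow_ml_min, temp_c, error_code` on
#'   the 1 Hz grid (absent chunks removed), with attribute `truth`.
#' @export
generate_waveform <- function(subject, config) {
  tl <- subject$timeline
  stopifnot(inherits(tl, "surgical_timeline"))
  t <- seq.int(tl$surgery_start_s, tl$surgery_end_s - 1L)
  n <- length(t)
  first_start <- tl$cpb_runs[[1]][1]
  last_end <- tl$cpb_runs[[length(tl$cpb_runs)]][2]

  mu_post <- config$mu_post - if (subject$aki) config$delta_mmHg else 0
  mu_step <- ifelse(t < first_start, config$mu_pre,
                    ifelse(t < last_end, config$mu_cpb, mu_post))
  mu <- ramp_transitions(mu_step, ramp_s = 300L)

  phi <- exp(-config$mean_reversion)
  innov_sd <- config$sd_within * sqrt(1 - phi^2)
  dev <- as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                                  method = "recursive",
                                  init = stats::rnorm(1, 0, config$sd_within)))
  puo2 <- pmax(0, mu + dev)

  # flow: slow log-scale AR(1) around the target urine output
  phi_f <- exp(-1 / 600)
  ldev <- as.numeric(stats::filter(stats::rnorm(n, 0, 0.45 * sqrt(1 - phi_f^2)),
                                   phi_f, method = "recursive",
                                   init = stats::rnorm(1, 0, 0.45)))
  flow <- config$flow_target_ml_kg_h * subject$weight_kg / 60 * exp(ldev)

  # temperature: cooled on pump, rewarmed after
  temp_step <- ifelse(t < first_start, 36.2, ifelse(t < last_end, 32, 36.2))
  temp <- ramp_transitions(temp_step, ramp_s = 900L) + stats::rnorm(n, 0, 0.05)

  truth <- list(error = integer(0), retrograde = integer(0),
                zero_flow = integer(0))

  # zero-flow (stagnant urine) episodes
  zf_start <- which(stats::runif(n) < config$zero_flow_rate)
  for (s in zf_start) {
    len <- max(1L, stats::rgeom(1, 1 / config$zero_flow_duration_s) + 1L)
    idx <- s:min(n, s + len - 1L)
    flow[idx] <- 0
    truth$zero_flow <- union(truth$zero_flow, t[idx])
  }

  # retrograde blips
  rg_start <- which(stats::runif(n) < config$retrograde_rate)
  for (s in rg_start) {
    len <- max(1L, stats::rgeom(1, 1 / config$retrograde_duration_s) + 1L)
    idx <- s:min(n, s + len - 1L)
    flow[idx] <- -stats::runif(length(idx), 0.5, 3)
    truth$retrograde <- union(truth$retrograde, t[idx])
  }

  # flow-sensor error codes
  err <- stats::runif(n) < config$error_code_rate
  error_code <- integer(n)
  error_code[err] <- sample(1:3, sum(err), replace = TRUE)
  truth$error <- t[err]

  wf <- data.frame(t_s = t, puo2_mmHg = puo2, flow_ml_min = flow,
                   temp_c = temp, error_code = error_code)

  # absent record chunks (device disconnected) per period
  bounds <- list(c(tl$surgery_start_s, first_start),
                 c(first_start, last_end),
                 c(last_end, tl$surgery_end_s))
  drop_idx <- integer(0)
  for (b in bounds) {
    if (stats::runif(1) < config$missing_period_prob) {
      plen <- b[2] - b[1]
      frac <- stats::runif(1, 0.5, 0.95)
      gap_len <- round(frac * plen)
      gap_start <- b[1] + sample.int(max(1L, plen - gap_len + 1L), 1) - 1L
      drop_idx <- c(drop_idx, which(t >= gap_start & t < gap_start + gap_len))
    }
  }
  if (length(drop_idx)) wf <- wf[-drop_idx, , drop = FALSE]
  rownames(wf) <- NULL
  attr(wf, "truth") <- lapply(truth, function(v) setdiff(v, t[drop_idx]))
  wf
}

# Linear 5-point-knot ramping of a step function: each level change is
# approached linearly over ramp_s samples instead of a jump.
ramp_transitions <- function(step, ramp_s) {
  n <- length(step)
  ch <- which(diff(step) != 0)
  if (!length(ch)) return(step)
  out <- step
  for (j in ch) {
    to <- step[j + 1L]
    from <- step[j]
    hi <- min(n, j + ramp_s)
    k <- seq.int(j + 1L, hi)
    out[k] <- pmin(1, (k - j) / ramp_s) * (to - from) + from
  }
  out
}
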