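#' Cohort generator configuration
#'
#' Builds the configuration object consumed by [generate_cohort()]. Defaults
#' describe a high-risk cardiac-surgery cohort: group-conditional demographics
#' (AKI vs no-AKI) with means/SDs and event proportions taken from published
#' cohort summaries, 1 Hz urine-oximetry waveform parameters, and artifact
#' injection rates.
#'
#' @param n_subjects number of subjects to generate.
#' @param aki_prevalence probability a subject carries the AKI label, in (0,1).
#' @param demographics two-element list (`aki`, `no_aki`) of group parameter
#'   lists; see Details. Defaults are the package's built-in cohort summary.
#' @param mu_pre,mu_cpb,mu_post target mean PuO2 (mmHg) for the pre-bypass,
#'   bypass, and post-bypass periods.
#' @param delta_mmHg post-bypass PuO2 deficit (mmHg) applied to AKI subjects;
#'   the generator's AKI effect size. Must be >= 0.
#' @param sd_within within-subject stationary SD of the PuO2 process (mmHg).
#' @param mean_reversion per-second mean-reversion rate of the PuO2 process;
#'   the AR(1) coefficient is `exp(-mean_reversion)`.
#' @param error_code_rate per-sample probability of a nonzero flow-sensor
#'   error code.
#' @param retrograde_rate per-second probability that a retrograde-flow blip
#'   starts.
#' @param retrograde_duration_s mean duration (s) of a retrograde blip.
#' @param zero_flow_rate per-second probability that a zero-flow episode
#'   starts.
#' @param zero_flow_duration_s mean duration (s) of a zero-flow episode.
#' @param missing_period_prob probability, per surgical period, that a
#'   contiguous chunk of the record is absent (device disconnected).
#' @param lvad_prob probability a subject carries a ventricular-assist-device
#'   flag (such subjects are excluded downstream).
#' @param flow_target_ml_kg_h median urine output target (mL/kg/h) of the
#'   flow process; its log-scale variability makes the subject's flow rate
#'   straddle the 0.5 mL/kg/h discard threshold occasionally.
#' @param rng_seed integer seed; fixed seed gives a bit-identical cohort.
#'
#' @details
#' Each group entry in `demographics` is a list with elements
#' `age` (mean, sd), `bmi` (mean, sd), `creatinine` (mean, sd),
#' `p_lvef_lt_35`, `p_diabetes`, `p_female`, `procedure` (named probability
#' vector over `isolated_cabg`, `single_valve`, `valve_plus_cabg`,
#' `multi_valve`, `other`), and `cpb_min` (mean, sd of total bypass minutes).
#'
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 73,
                          aki_prevalence = 46 / 73,
                          demographics = default_demographics(),
                          mu_pre = 50,
                          mu_cpb = 42,
                          mu_post = 38,
                          delta_mmHg = 10,
                          sd_within = 8,
                          mean_reversion = 0.005,
                          error_code_rate = 0.002,
                          retrograde_rate = 5e-5,
                          retrograde_duration_s = 5,
                          zero_flow_rate = 1e-4,
                          zero_flow_duration_s = 120,
                          missing_period_prob = 0.05,
                          lvad_prob = 0.03,
                          flow_target_ml_kg_h = 1.2,
                          rng_seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop("n_subjects must be a positive integer")
  if (!is.numeric(aki_prevalence) || aki_prevalence <= 0 || aki_prevalence >= 1)
    stop("aki_prevalence must lie in (0, 1)")
  if (delta_mmHg < 0) stop("delta_mmHg must be >= 0")
  rates <- c(error_code_rate, retrograde_rate, zero_flow_rate,
             missing_period_prob, lvad_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  stopifnot(is.list(demographics), all(c("aki", "no_aki") %in% names(demographics)))
  structure(list(
    n_subjects = as.integer(n_subjects),
    aki_prevalence = aki_prevalence,
    demographics = demographics,
    mu_pre = mu_pre, mu_cpb = mu_cpb, mu_post = mu_post,
    delta_mmHg = delta_mmHg,
    sd_within = sd_within,
    mean_reversion = mean_reversion,
    error_code_rate = error_code_rate,
    retrograde_rate = retrograde_rate,
    retrograde_duration_s = retrograde_duration_s,
    zero_flow_rate = zero_flow_rate,
    zero_flow_duration_s = zero_flow_duration_s,
    missing_period_prob = missing_period_prob,
    lvad_prob = lvad_prob,
    flow_target_ml_kg_h = flow_target_ml_kg_h,
    rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Default group-conditional demographic parameters
#'
#' Group means/SDs and event proportions for the AKI and no-AKI groups of a
#' high-risk cardiac-surgery cohort (46 AKI / 27 no-AKI): age, body mass
#' index, baseline creatinine, LVEF<35% and insulin-dependent-diabetes
#' proportions, sex, procedure mix, and total bypass minutes.
#'
#' @return list with elements `aki` and `no_aki`.
#' @export
default_demographics <- function() {
  proc_levels <- c("isolated_cabg", "single_valve", "valve_plus_cabg",
                   "multi_valve", "other")
  aki_proc <- c(16, 9, 7, 5, 7); names(aki_proc) <- proc_levels
  no_proc <- c(7, 6, 3, 3, 7); names(no_proc) <- proc_levels
  list(
    aki = list(
      age = c(mean = 65, sd = 11),
      bmi = c(mean = 29.38, sd = 5.89),
      creatinine = c(mean = 1.12, sd = 0.26),
      p_lvef_lt_35 = 7 / 46,
      p_diabetes = 14 / 46,
      p_female = 14 / 46,
      procedure = aki_proc / sum(aki_proc),
      cpb_min = c(mean = 160.42, sd = 55.28)
    ),
    no_aki = list(
      age = c(mean = 62, sd = 15),
      bmi = c(mean = 26.57, sd = 5.32),
      creatinine = c(mean = 0.97, sd = 0.25),
      p_lvef_lt_35 = 2 / 27,
      p_diabetes = 1 / 27,
      p_female = 8 / 27,
      procedure = no_proc / sum(no_proc),
      cpb_min = c(mean = 167.74, sd = 70.25)
    )
  )
}

#' Waveform QC configuration
#'
#' Thresholds for the artifact-discard rules applied by [compute_qc_mask()]
#' and the period missingness rule of [period_validity()].
#'
#' @param flow_threshold_ml_kg_h low-flow discard threshold; samples whose
#'   trailing-window mean urine output falls strictly below it are discarded.
#' @param max_missing_fraction a period is dropped when its missing fraction
#'   strictly exceeds this value.
#' @param stagnation_s a maximal zero-flow run strictly longer than this many
#'   seconds is treated as stagnant urine.
#' @param retrograde_guard_s samples within this many seconds of a negative
#'   flow sample are discarded together with it.
#' @param flow_window_s trailing window (s) for the low-flow mean.
#' @param zero_flow_eps flows with absolute value below this (mL/min) count
#'   as zero flow.
#'
#' @return list of class `qc_config`.
#' @export
qc_config <- function(flow_threshold_ml_kg_h = 0.5,
                      max_missing_fraction = 0.70,
                      stagnation_s = 60,
                      retrograde_guard_s = 30,
                      flow_window_s = 600,
                      zero_flow_eps = 0.01) {
  stopifnot(flow_threshold_ml_kg_h >= 0, max_missing_fraction >= 0,
            max_missing_fraction <= 1, stagnation_s >= 0,
            retrograde_guard_s >= 0, flow_window_s >= 1, zero_flow_eps >= 0)
  structure(list(
    flow_threshold_ml_kg_h = flow_threshold_ml_kg_h,
    max_missing_fraction = max_missing_fraction,
    stagnation_s = stagnation_s,
    retrograde_guard_s = retrograde_guard_s,
    flow_window_s = flow_window_s,
    zero_flow_eps = zero_flow_eps
  ), class = "qc_config")
}

#' Bagged-SVM model configuration
#'
#' @param n_estimators number of base support vector machines (>= 1).
#' @param kernel `"rbf"` or `"linear"`.
#' @param cost SVM regularization parameter C.
#' @param gamma RBF kernel scale; `NULL` uses `1 / (p * var(X))` computed on
#'   the standardized training matrix.
#' @param rng_seed integer seed for the bootstrap resamples.
#'
#' @return list of class `model_config`.
#' @export
model_config <- function(n_estimators = 100L,
                         kernel = c("rbf", "linear"),
                         cost = 1,
                         gamma = NULL,
                         rng_seed = 1L) {
  kernel <- match.arg(kernel)
  if (!is.numeric(n_estimators) || n_estimators < 1)
    stop("n_estimators must be >= 1")
  structure(list(
    n_estimators = as.integer(n_estimators),
    kernel = kernel,
    cost = cost,
    gamma = gamma,
    rng_seed = as.integer(rng_seed)
  ), class = "model_config")
}

#' Full pipeline configuration
#'
#' One document that fully determines a pipeline run; serializable to
#' YAML/JSON via [write_run_config()] / [read_run_config()].
#'
#' @param cohort a [cohort_config()].
#' @param qc a [qc_config()].
#' @param thresholds PuO2 threshold grid (mmHg) for exposure features.
#' @param alpha significance level of the forward-selection entry test.
#' @param model a [model_config()].
#' @param nested_selection re-run feature selection inside every
#'   cross-validation fold (honest error estimation) instead of once on the
#'   full dataset.
#' @param seed global seed; stage seeds are derived from it.
#'
#' @return list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       qc = qc_config(),
                       thresholds = c(15, 25, 35),
                       alpha = 0.05,
                       model = model_config(),
                       nested_selection = FALSE,
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(qc, "qc_config"),
            inherits(model, "model_config"), length(thresholds) >= 1,
            alpha > 0, alpha < 1)
  seed <- as.integer(seed)
  cohort$rng_seed <- derive_seed(seed, 1L)
  model$rng_seed <- derive_seed(seed, 2L)
  structure(list(
    cohort = cohort, qc = qc, thresholds = thresholds, alpha = alpha,
    model = model, nested_selection = isTRUE(nested_selection),
    seed = seed
  ), class = "run_config")
}

#' Read / write a pipeline configuration
#'
#' @param path YAML (`.yaml`/`.yml`) or JSON file.
#' @param config a [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config(seed = raw$seed %||% 1L)
  for (nm in intersect(names(raw$cohort), names(cfg$cohort)))
    if (nm != "demographics") cfg$cohort[[nm]] <- raw$cohort[[nm]]
  for (nm in intersect(names(raw$qc), names(cfg$qc)))
    cfg$qc[[nm]] <- raw$qc[[nm]]
  for (nm in intersect(names(raw$model), names(cfg$model)))
    cfg$model[[nm]] <- raw$model[[nm]]
  if (!is.null(raw$thresholds)) cfg$thresholds <- as.numeric(raw$thresholds)
  if (!is.null(raw$alpha)) cfg$alpha <- raw$alpha
  if (!is.null(raw$nested_selection))
    cfg$nested_selection <- isTRUE(raw$nested_selection)
  cfg
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else unclass(x)
  }
  plain <- strip(config)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(plain, path)
  else jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE)
  invisible(path)
}
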