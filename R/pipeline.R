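#' Write / read a cohort as plain CSV/JSON artifacts
#'
#' `write_cohort` writes `cohort.csv` (one row per subject: demographics,
#' label, waveform filename), one waveform CSV per subject
#' (`t_s,puo2_mmHg,flow_ml_min,temp_c,error_code`), and one timeline JSON
#' per subject (`surgery_start_s`, `surgery_end_s`, `cpb_runs`). Injected
#' artifact truth masks, when present, go to `truth/<id>.json`.
#' `read_cohort` reads them back; `read(write(x))` reproduces `x`.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `write_cohort`: `dir`, invisibly. `read_cohort`: a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "waveforms"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "timelines"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    data.frame(subject_id = s$subject_id, age_y = s$age_y, sex = s$sex,
               bmi = s$bmi, weight_kg = s$weight_kg,
               baseline_creatinine_mg_dl = s$baseline_creatinine_mg_dl,
               insulin_dep_diabetes = s$insulin_dep_diabetes,
               lvef_lt_35 = s$lvef_lt_35,
               procedure_type = s$procedure_type, lvad = s$lvad,
               aki = s$aki,
               waveform_file = file.path("waveforms",
                                         paste0(s$subject_id, ".csv")),
               timeline_file = file.path("timelines",
                                         paste0(s$subject_id, ".json")),
               stringsAsFactors = FALSE)
  })
  data.table::fwrite(do.call(rbind, rows), file.path(dir, "cohort.csv"))
  for (s in cohort$subjects) {
    data.table::fwrite(s$waveform,
                       file.path(dir, "waveforms",
                                 paste0(s$subject_id, ".csv")))
    tl <- s$timeline
    jsonlite::write_json(
      list(surgery_start_s = tl$surgery_start_s,
           surgery_end_s = tl$surgery_end_s,
           cpb_runs = lapply(tl$cpb_runs, as.integer)),
      file.path(dir, "timelines", paste0(s$subject_id, ".json")),
      auto_unbox = TRUE, digits = NA)
    truth <- attr(s$waveform, "truth")
    if (!is.null(truth))
      jsonlite::write_json(truth,
                           file.path(dir, "truth",
                                     paste0(s$subject_id, ".json")),
                           digits = NA)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "cohort.csv")
  if (!file.exists(path)) stop("no cohort.csv in ", dir)
  tab <- as.data.frame(data.table::fread(path))
  need <- c("subject_id", "age_y", "sex", "bmi", "weight_kg",
            "baseline_creatinine_mg_dl", "insulin_dep_diabetes",
            "lvef_lt_35", "procedure_type", "lvad", "aki",
            "waveform_file", "timeline_file")
  if (!all(need %in% names(tab)))
    stop("cohort.csv lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  subjects <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    tl <- jsonlite::read_json(file.path(dir, r$timeline_file),
                              simplifyVector = TRUE)
    runs <- tl$cpb_runs
    if (is.matrix(runs)) runs <- lapply(seq_len(nrow(runs)), function(k)
      as.integer(runs[k, ]))
    if (length(runs) == 0L)
      stop("subject ", r$subject_id, ": timeline has no bypass runs")
    timeline <- structure(list(surgery_start_s = as.integer(tl$surgery_start_s),
                               surgery_end_s = as.integer(tl$surgery_end_s),
                               cpb_runs = runs),
                          class = "surgical_timeline")
    wf <- as.data.frame(data.table::fread(file.path(dir, r$waveform_file)))
    wneed <- c("t_s", "puo2_mmHg", "flow_ml_min", "temp_c", "error_code")
    if (!all(wneed %in% names(wf)))
      stop("subject ", r$subject_id, ": waveform lacks columns ",
           paste(setdiff(wneed, names(wf)), collapse = ", "))
    if (any(diff(wf$t_s) < 1))
      stop("subject ", r$subject_id, ": non-monotone timestamps at line ",
           which(diff(wf$t_s) < 1)[1] + 1L)
    if (min(wf$t_s) < timeline$surgery_start_s ||
        max(wf$t_s) >= timeline$surgery_end_s)
      stop("subject ", r$subject_id, ": waveform outside the surgery window")
    tr_path <- file.path(dir, "truth", paste0(r$subject_id, ".json"))
    if (file.exists(tr_path))
      attr(wf, "truth") <- lapply(jsonlite::read_json(tr_path,
                                                      simplifyVector = TRUE),
                                  as.integer)
    structure(list(subject_id = r$subject_id, age_y = r$age_y, sex = r$sex,
                   bmi = r$bmi, weight_kg = r$weight_kg,
                   baseline_creatinine_mg_dl = r$baseline_creatinine_mg_dl,
                   insulin_dep_diabetes = r$insulin_dep_diabetes,
                   lvef_lt_35 = r$lvef_lt_35,
                   procedure_type = r$procedure_type, lvad = r$lvad,
                   aki = r$aki, timeline = timeline, waveform = wf),
              class = "subject_record")
  })
  structure(list(subjects = subjects, config = NULL), class = "cohort")
}

#' Select features and evaluate both models under LOOCV
#'
#' Runs the two selection procedures (forward stepwise logistic selection
#' of preoperative features; maximum-AUROC choice of a single PuO2
#' feature), then computes leave-one-out cross-validated probabilities for
#' the preoperative-only and preoperative + PuO2 models and compares them.
#' By default selection runs once on the full dataset before
#' cross-validation; `nested = TRUE` instead repeats the selection inside
#' every fold on its training subjects only (honest but more variable).
#'
#' @param features complete-case feature table (rows = included subjects)
#'   with `subject_id`, `aki`, and feature columns carrying a
#'   `feature_meta` attribute.
#' @param alpha forward-selection entry level.
#' @param model a [model_config()].
#' @param nested nested (per-fold) selection.
#' @return list of class `model_evaluation`: `selection` (retained preop
#'   features, best PuO2 feature and its AUROC, step log), `loocv_preop`,
#'   `loocv_combined`, `comparison`.
#' @export
evaluate_models <- function(features, alpha = 0.05,
                            model = model_config(), nested = FALSE) {
  y <- as_binary(features$aki)
  preop <- intersect(preop_feature_names(features), names(features))
  puo2 <- intersect(puo2_feature_names(features), names(features))
  if (!length(preop) || !length(puo2))
    stop("feature table must carry preop and puo2 feature metadata")
  Xp <- features[, preop, drop = FALSE]
  usable <- names(Xp)[vapply(Xp, function(c) length(unique(c)) > 1L,
                             logical(1))]
  if (!nested) {
    sel <- forward_select(features[, usable, drop = FALSE], y, alpha)
    # a void preoperative model has no covariates; fall back to the single
    # best-p candidate so the bagged classifier has an input
    preop_set <- sel$retained
    if (!length(preop_set)) {
      p1 <- vapply(usable, function(f)
        fit_logistic(y, features[, f, drop = FALSE])$p_values[2], numeric(1))
      preop_set <- names(sort(p1))[1]
    }
    best <- best_puo2_feature(features[, puo2, drop = FALSE], y)
    loocv_a <- loocv_probabilities(features, y, preop_set, model,
                                   model_tag = "preop_only")
    loocv_b <- loocv_probabilities(features, y, c(preop_set, best$name),
                                   model, model_tag = "preop_plus_puo2")
    selection <- list(retained_preop = preop_set, step_log = sel$step_log,
                      best_puo2 = best$name, best_puo2_auroc = best$auroc,
                      puo2_aurocs = best$aurocs, alpha = alpha,
                      nested = FALSE)
  } else {
    n <- nrow(features)
    pa <- pb <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      ytr <- y[tr]
      us_i <- usable[vapply(usable, function(f)
        length(unique(features[tr, f])) > 1L, logical(1))]
      sel_i <- suppressWarnings(
        forward_select(features[tr, us_i, drop = FALSE], ytr, alpha))
      set_i <- sel_i$retained
      if (!length(set_i)) {
        p1 <- vapply(us_i, function(f)
          fit_logistic(ytr, features[tr, f, drop = FALSE])$p_values[2],
          numeric(1))
        set_i <- names(sort(p1))[1]
      }
      best_i <- best_puo2_feature(features[tr, puo2, drop = FALSE], ytr)
      cfg <- model
      cfg$rng_seed <- derive_seed(model$rng_seed, i)
      ma <- train_bagged_svm(as.matrix(features[tr, set_i, drop = FALSE]),
                             ytr, cfg)
      mb <- train_bagged_svm(
        as.matrix(features[tr, c(set_i, best_i$name), drop = FALSE]),
        ytr, cfg)
      pa[i] <- predict_probability(ma,
        as.matrix(features[i, set_i, drop = FALSE]))
      pb[i] <- predict_probability(mb,
        as.matrix(features[i, c(set_i, best_i$name), drop = FALSE]))
    }
    mk <- function(prob, tag) {
      out <- data.frame(subject_id = features$subject_id, label = y,
                        prob = prob, fold = seq_len(n), degenerate = FALSE,
                        stringsAsFactors = FALSE)
      attr(out, "model_tag") <- tag
      class(out) <- c("loocv_result", "data.frame")
      out
    }
    loocv_a <- mk(pa, "preop_only")
    loocv_b <- mk(pb, "preop_plus_puo2")
    selection <- list(retained_preop = NULL, step_log = NULL,
                      best_puo2 = NULL, best_puo2_auroc = NULL,
                      alpha = alpha, nested = TRUE)
  }
  structure(list(selection = selection, loocv_preop = loocv_a,
                 loocv_combined = loocv_b,
                 comparison = compare_models(loocv_a, loocv_b)),
            class = "model_evaluation")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> QC -> features -> subject filtering -> selection ->
#' LOOCV evaluation -> paired comparison, writing every intermediate
#' artifact as plain CSV/JSON plus a manifest. Reruns with the same config
#' produce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory; created if needed. `NULL`
#'   keeps everything in memory and writes nothing.
#' @return list of class `pipeline_run`: `cohort`, `features` (complete
#'   rows), `filter`, `evaluation`, `univariate`, `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- generate_cohort(config$cohort)
  features <- build_feature_table(cohort, qc = config$qc,
                                  thresholds = config$thresholds)
  flt <- filter_cohort(cohort, features)
  keep <- features$subject_id %in% flt$included
  feats_in <- features[keep, , drop = FALSE]
  attr(feats_in, "feature_meta") <- attr(features, "feature_meta")
  if (length(unique(feats_in$aki)) < 2L)
    stop("stage evaluate: included subjects form a single outcome class")
  evaluation <- evaluate_models(feats_in, alpha = config$alpha,
                                model = config$model,
                                nested = config$nested_selection)
  uni <- univariate_table(cohort)

  manifest <- list(
    seed = config$seed,
    n_generated = length(cohort$subjects),
    n_excluded_lvad = sum(flt$log$reason == "lvad"),
    n_excluded_missing = sum(flt$log$reason == "missing_features"),
    n_included = length(flt$included),
    retained_preop = evaluation$selection$retained_preop,
    best_puo2 = evaluation$selection$best_puo2,
    stages = c("simulate", "qc", "features", "select", "evaluate", "report")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    data.table::fwrite(features, file.path(out_dir, "features.csv"))
    data.table::fwrite(flt$log, file.path(out_dir, "exclusions.csv"))
    probs <- data.frame(subject_id = evaluation$loocv_preop$subject_id,
                        label = evaluation$loocv_preop$label,
                        p_preop = evaluation$loocv_preop$prob,
                        p_combined = evaluation$loocv_combined$prob)
    data.table::fwrite(probs, file.path(out_dir, "probabilities.csv"))
    jsonlite::write_json(selection_to_list(evaluation$selection),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_report(report_list(evaluation, uni, manifest),
                 file.path(out_dir, "report.json"))
    cfg_file <- file.path(out_dir, "config.json")
    write_run_config(config, cfg_file)
    manifest$config_md5 <- unname(tools::md5sum(cfg_file))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  structure(list(cohort = cohort, features = feats_in, filter = flt,
                 evaluation = evaluation, univariate = uni,
                 manifest = manifest),
            class = "pipeline_run")
}

selection_to_list <- function(sel) {
  list(retained_preop = as.list(sel$retained_preop),
       best_puo2 = sel$best_puo2,
       best_puo2_auroc = sel$best_puo2_auroc,
       alpha = sel$alpha, nested = sel$nested,
       step_log = sel$step_log)
}

report_list <- function(evaluation, univariate, manifest) {
  cmp <- evaluation$comparison
  list(
    models = list(a = cmp$model_a, b = cmp$model_b),
    auroc = list(preop_only = cmp$roc$auroc_a,
                 preop_plus_puo2 = cmp$roc$auroc_b,
                 ci_preop_only = cmp$roc$ci_a,
                 ci_preop_plus_puo2 = cmp$roc$ci_b),
    delong = list(z = cmp$roc$delong_z, p = cmp$roc$delong_p),
    confusion = list(
      preop_only = unclass(cmp$confusion_a)[c("tp", "fp", "tn", "fn",
                                              "sensitivity", "specificity")],
      preop_plus_puo2 = unclass(cmp$confusion_b)[c("tp", "fp", "tn", "fn",
                                                   "sensitivity",
                                                   "specificity")]),
    mcnemar = list(sensitivity_p = cmp$mcnemar_p_sensitivity,
                   specificity_p = cmp$mcnemar_p_specificity),
    selection = selection_to_list(evaluation$selection),
    univariate = univariate,
    counts = manifest[c("n_generated", "n_excluded_lvad",
                        "n_excluded_missing", "n_included")]
  )
}

#' Write / read a comparison report as JSON
#'
#' @param report list as produced inside [run_pipeline()].
#' @param path output JSON path.
#' @return `write_report`: `path` invisibly; `read_report`: the list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' One-call synthetic study
#'
#' Convenience wrapper: builds a [run_config()] for the stated study
#' conditions, runs [run_pipeline()], and returns the run.
#'
#' @param n cohort size. @param prevalence AKI prevalence.
#' @param delta post-bypass PuO2 deficit (mmHg) for AKI subjects.
#' @param seed global seed.
#' @param ... passed on to [run_config()].
#' @return a `pipeline_run`.
#' @export
run_study <- function(n = 73, prevalence = 46 / 73, delta = 10, seed = 1L,
                      ...) {
  cfg <- run_config(cohort = cohort_config(n_subjects = n,
                                           aki_prevalence = prevalence,
                                           delta_mmHg = delta),
                    seed = seed, ...)
  run_pipeline(cfg)
}
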