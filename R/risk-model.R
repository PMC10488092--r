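#' Train a bagged support-vector-machine classifier
#'
#' Fits `n_estimators` base SVMs, each on a bootstrap resample of the
#' training set (size N, drawn with replacement; a resample containing a
#' single class is redrawn, with a bounded number of retries). Features are
#' z-scored with training-set means/SDs stored in the model (constant
#' columns get unit scale). The RBF kernel scale defaults to
#' `1 / (p * var)` with `var` the overall variance of the standardized
#' training matrix. Per-estimator bootstrap seeds derive deterministically
#' from the config seed, so identical inputs give identical models.
#'
#' @param X numeric matrix or data.frame of predictors (no missing values).
#' @param y binary outcome (1 = case); both classes required.
#' @param config a [model_config()].
#' @return object of class `bagged_svm`: base estimators plus the stored
#'   standardization parameters.
#' @export
train_bagged_svm <- function(X, y, config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  y <- as_binary(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must be complete")
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  center <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ == 0 | is.na(scale_)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scale_, "/")
  v <- stats::var(as.vector(Z))
  gamma <- config$gamma %||% (if (is.finite(v) && v > 0) 1 / (p * v) else 1 / p)
  kern <- if (config$kernel == "rbf") "radial" else "linear"
  yf <- factor(y, levels = c(0L, 1L))
  estimators <- vector("list", config$n_estimators)
  for (b in seq_len(config$n_estimators)) {
    set.seed(derive_seed(config$rng_seed, b))
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (length(unique(y[idx])) < 2L) {
      tries <- tries + 1L
      if (tries > 100L) stop("could not draw a two-class bootstrap resample")
      idx <- sample.int(n, n, replace = TRUE)
    }
    estimators[[b]] <- e1071::svm(Z[idx, , drop = FALSE], yf[idx],
                                  type = "C-classification", kernel = kern,
                                  cost = config$cost, gamma = gamma,
                                  scale = FALSE)
  }
  structure(list(estimators = estimators, center = center, scale = scale_,
                 gamma = gamma, config = config, p = p),
            class = "bagged_svm")
}

#' Predicted AKI probability from a bagged SVM
#'
#' The probability is the vote share: the fraction of base classifiers
#' predicting the positive class. It therefore lies on the grid
#' `{0, 1/B, ..., 1}` for `B` estimators. Inputs are standardized with the
#' parameters stored at training time.
#'
#' @param model a `bagged_svm`.
#' @param x numeric matrix (rows = subjects) or a single feature vector on
#'   the original (unstandardized) scale.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict_probability <- function(model, x) {
  stopifnot(inherits(model, "bagged_svm"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != model$p) stop("feature dimension mismatch")
  Z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  votes <- vapply(model$estimators, function(m)
    as.integer(as.character(predict(m, Z))), integer(nrow(Z)))
  if (nrow(Z) == 1L) votes <- matrix(votes, nrow = 1)
  rowMeans(votes)
}

#' Leave-one-out cross-validated probabilities
#'
#' For each subject, the model is trained on the other N-1 subjects
#' (standardization parameters included) and predicts the held-out
#' subject's probability, so no fold's prediction depends on its own label
#' or feature row beyond the input vector itself. Per-fold seeds derive
#' from `(rng_seed, fold)`, making fold order irrelevant.
#'
#' @param features data.frame with `subject_id` and feature columns (as
#'   from [build_feature_table()]).
#' @param y binary outcome aligned to `features` rows.
#' @param feature_set character vector of feature column names to use.
#' @param config a [model_config()].
#' @param model_tag label stored on the result (e.g. `"preop_only"`).
#' @return data.frame of class `loocv_result`: `subject_id`, `label`,
#'   `prob`, `fold`, `degenerate` (fold training set had one class).
#' @export
loocv_probabilities <- function(features, y, feature_set,
                                config = model_config(),
                                model_tag = "model") {
  y <- as_binary(y)
  missing_cols <- setdiff(feature_set, names(features))
  if (length(missing_cols))
    stop("unknown features: ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(features[, feature_set, drop = FALSE])
  if (anyNA(X)) stop("feature set must be complete cases")
  n <- nrow(X)
  if (n < 4L) stop("need at least 4 subjects for leave-one-out")
  ids <- if ("subject_id" %in% names(features)) features$subject_id
         else sprintf("row%03d", seq_len(n))
  prob <- rep(NA_real_, n)
  degenerate <- logical(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      degenerate[i] <- TRUE
      next
    }
    cfg <- config
    cfg$rng_seed <- derive_seed(config$rng_seed, i)
    m <- train_bagged_svm(X[-i, , drop = FALSE], ytr, cfg)
    prob[i] <- predict_probability(m, X[i, , drop = FALSE])
  }
  out <- data.frame(subject_id = ids, label = y, prob = prob,
                    fold = seq_len(n), degenerate = degenerate,
                    stringsAsFactors = FALSE)
  attr(out, "model_tag") <- model_tag
  class(out) <- c("loocv_result", "data.frame")
  out
}
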