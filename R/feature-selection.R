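#' Fit a binary logistic regression
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' [stats::glm()], tight convergence tolerance, 100 iterations) with Wald
#' p-values and a complete/quasi-separation flag raised when fitted
#' probabilities collapse to 0/1 or coefficients diverge.
#'
#' @param y binary outcome (0/1, logical, or two-level factor).
#' @param X design matrix or data.frame of predictors (no intercept column;
#'   one is added).
#' @return list of class `logistic_fit`: `coefficients`, `se`, `p_values`
#'   (Wald, vs standard normal), `converged`, `separation_flag`, `fit`.
#' @examples
#' fit_logistic(c(0, 1, 1, 1), matrix(nrow = 4, ncol = 0))$coefficients
#' @export
fit_logistic <- function(y, X) {
  y <- as_binary(y)
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  X <- as.matrix(X)
  if (ncol(X) > 0) {
    if (any(apply(X, 2, function(c) length(unique(c)) == 1L)))
      stop("design matrix contains a constant column")
    if (qr(cbind(1, X))$rank < ncol(X) + 1L)
      stop("design matrix is rank deficient")
  }
  dat <- data.frame(.y = y)
  if (ncol(X) > 0) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    dat <- cbind(dat, as.data.frame(X))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  separation <- sep_warn || any(abs(stats::coef(fit)) > 15) || !fit$converged
  structure(list(
    coefficients = stats::coef(fit),
    se = sm[, "Std. Error"],
    p_values = sm[, "Pr(>|z|)"],
    converged = fit$converged,
    separation_flag = separation,
    fit = fit
  ), class = "logistic_fit")
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(as.logical(y) | y == 1)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary")
  y
}

#' Forward stepwise logistic selection of preoperative features
#'
#' At each step every remaining candidate is added, in turn, to the current
#' model; its score is the Wald p-value of its coefficient in that expanded
#' model. The smallest-p candidate enters if its p-value is below `alpha`,
#' and the process repeats; it stops when no candidate qualifies. No
#' backward elimination is performed; if a previously retained feature's
#' p-value rises to `alpha` or above, a warning is emitted and the feature
#' kept.
#'
#' @param features data.frame (or matrix) of candidate predictors,
#'   complete cases only.
#' @param y binary outcome.
#' @param alpha entry significance level, in (0, 1); default 0.05.
#' @return list of class `selection_result`: `retained` (ordered names),
#'   `step_log` (list of per-step data.frames `candidate, p_value, chosen`),
#'   `alpha`.
#' @export
forward_select <- function(features, y, alpha = 0.05) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  y <- as_binary(y)
  X <- as.matrix(features)
  if (anyNA(X)) stop("features must be complete cases")
  candidates <- colnames(X)
  retained <- character(0)
  step_log <- list()
  repeat {
    remaining <- setdiff(candidates, retained)
    if (!length(remaining)) break
    pvals <- vapply(remaining, function(f) {
      fit <- try(fit_logistic(y, X[, c(retained, f), drop = FALSE]),
                 silent = TRUE)
      if (inherits(fit, "try-error")) return(NA_real_)
      unname(fit$p_values[length(fit$p_values)])
    }, numeric(1))
    if (all(is.na(pvals))) break
    best <- remaining[which.min(pvals)]
    step <- data.frame(candidate = remaining, p_value = unname(pvals),
                       chosen = remaining == best &
                         !is.na(pvals) & pvals == min(pvals, na.rm = TRUE),
                       stringsAsFactors = FALSE)
    if (is.na(pvals[which.min(pvals)]) || min(pvals, na.rm = TRUE) >= alpha) {
      step$chosen <- FALSE
      step_log[[length(step_log) + 1L]] <- step
      break
    }
    step_log[[length(step_log) + 1L]] <- step
    retained <- c(retained, best)
    full <- fit_logistic(y, X[, retained, drop = FALSE])
    p_now <- full$p_values[-1]
    if (any(p_now >= alpha))
      warning("retained feature(s) no longer significant: ",
              paste(retained[p_now >= alpha], collapse = ", "))
  }
  structure(list(retained = retained, step_log = step_log, alpha = alpha),
            class = "selection_result")
}

#' Univariate AUROC of one feature
#'
#' Mann-Whitney probability that a random case outscores a random control,
#' ties credited one half. The feature is scored in its natural direction
#' (no reorientation).
#'
#' @param values numeric feature values, one per subject.
#' @param y binary outcome (1 = case).
#' @return AUROC in \[0, 1\].
#' @examples
#' univariate_auroc(c(3, 1, 2, 4), c(0, 1, 0, 1))  # 0.75
#' @export
univariate_auroc <- function(values, y) {
  y <- as_binary(y)
  if (length(values) != length(y)) stop("length mismatch")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(values)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pick the best PuO2 feature by univariate AUROC
#'
#' Scores every PuO2-derived feature with [univariate_auroc()] and returns
#' the maximizer; exactly one PuO2 feature joins the combined model. Ties
#' are broken by lexicographic feature name.
#'
#' @param features data.frame of PuO2 feature columns (complete cases).
#' @param y binary outcome.
#' @return list: `name`, `auroc`, and `aurocs` (named vector over all
#'   candidates).
#' @export
best_puo2_feature <- function(features, y) {
  X <- as.matrix(features)
  if (ncol(X) == 0L) stop("no PuO2 features supplied")
  if (anyNA(X)) stop("features must be complete cases")
  aurocs <- vapply(colnames(X), function(f) univariate_auroc(X[, f], y),
                   numeric(1))
  best <- sort(names(aurocs)[aurocs == max(aurocs)])[1]
  list(name = best, auroc = unname(aurocs[best]), aurocs = aurocs)
}
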