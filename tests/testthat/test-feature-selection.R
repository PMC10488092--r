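test_that("logistic fit recovers closed-form and flags degeneracies", {
  # intercept-only: logit of 3/4
  f <- fit_logistic(c(0, 1, 1, 1), matrix(nrow = 4, ncol = 0))
  expect_equal(unname(f$coefficients), log(3), tolerance = 1e-6)
  expect_true(f$converged)

  # perfectly separable -> separation flag
  fs <- fit_logistic(c(0, 0, 1, 1), matrix(1:4, ncol = 1))
  expect_true(fs$separation_flag)

  expect_error(fit_logistic(c(1, 1, 1, 1), matrix(1:4, ncol = 1)),
               "both classes")
  expect_error(fit_logistic(c(0, 1, 0, 1), matrix(1, 4, 1)), "constant")
  X <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8))
  expect_error(fit_logistic(c(0, 1, 0, 1), X), "rank deficient")
})

test_that("forward selection retains a strong predictor and obeys alpha", {
  set.seed(404)
  n <- 200
  x1 <- rnorm(n)
  X <- cbind(x1 = x1, x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  y <- rbinom(n, 1, plogis(2 * x1))
  sel <- suppressWarnings(forward_select(X, y))
  expect_gte(length(sel$retained), 1)
  expect_equal(sel$retained[1], "x1")
  expect_lte(length(sel$retained), 2)
  # entry p-values of everything retained were below alpha
  for (k in seq_along(sel$retained)) {
    step <- sel$step_log[[k]]
    expect_lt(step$p_value[step$chosen], sel$alpha)
  }
  expect_error(forward_select(X, y, alpha = 1.5), "alpha")
})

test_that("forward selection path equals a brute-force refit oracle", {
  set.seed(77)
  for (rep in 1:8) {
    n <- 120
    k <- sample(3:6, 1)
    X <- matrix(rnorm(n * k), n, k,
                dimnames = list(NULL, paste0("f", seq_len(k))))
    beta <- c(1.5, 0.8, rep(0, k - 2)) * sample(c(-1, 1), k, replace = TRUE)
    y <- rbinom(n, 1, plogis(X %*% beta))
    if (length(unique(y)) < 2) next
    sel <- suppressWarnings(forward_select(X, y))
    oracle <- suppressWarnings(forward_select_oracle(X, y))
    expect_identical(sel$retained, oracle)
  }
})

test_that("all-noise candidates are rarely retained (family-wise type I)", {
  hits <- 0L
  for (seed in 1:50) {
    set.seed(seed)
    n <- 200
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("z", 1:4)))
    y <- rbinom(n, 1, 0.5)
    sel <- suppressWarnings(forward_select(X, y))
    if (length(sel$retained) > 0) hits <- hits + 1L
  }
  # family-wise false-entry rate around 1-(1-.05)^4 ~ 0.19; demand < 50%
  expect_lt(hits / 50, 0.5)
})

test_that("a single candidate enters iff its p-value is below alpha", {
  set.seed(12)
  n <- 80
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(0.45 * x))
  X <- cbind(x = x)
  p <- fit_logistic(y, X)$p_values["x"]
  expect_true(p > 0.001 && p < 0.5)  # representative mid-range p
  above <- forward_select(X, y, alpha = min(0.999, p * 1.1))
  below <- forward_select(X, y, alpha = p * 0.9)
  expect_identical(above$retained, "x")
  expect_identical(below$retained, character(0))
})

test_that("univariate AUROC matches enumeration, ties and symmetry", {
  expect_equal(univariate_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(univariate_auroc(c(1, 1), c(0, 1)), 0.5)
  # enumeration: cases {1, 4} vs controls {3, 2} -> 2 of 4 pairs concordant
  expect_equal(univariate_auroc(c(3, 1, 2, 4), c(0, 1, 0, 1)), 0.5)
  expect_equal(univariate_auroc(c(3, 1, 2, 4), c(0, 1, 0, 1)),
               auroc_pairs(c(3, 1, 2, 4), c(0, 1, 0, 1)))

  set.seed(8)
  for (rep in 1:10) {
    v <- rnorm(30)
    y <- rbinom(30, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(univariate_auroc(v, y), auroc_pairs(v, y))
    # complement identity for tie-free values
    expect_equal(univariate_auroc(v, y) + univariate_auroc(-v, y), 1)
    # invariance under strictly monotone transform
    expect_equal(univariate_auroc(exp(v), y), univariate_auroc(v, y))
  }
  expect_error(univariate_auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("best PuO2 feature is the AUROC argmax with name tie-break", {
  y <- c(0, 0, 1, 1, 0, 1)
  f <- data.frame(b_weak = c(5, 1, 4, 2, 3, 6),
                  a_dup = c(1, 2, 3, 4, 5, 6),
                  c_dup = c(1, 2, 3, 4, 5, 6))
  best <- best_puo2_feature(f, y)
  expect_equal(best$name, "a_dup")   # ties on max AUROC -> first sorted name
  expect_equal(best$auroc, univariate_auroc(f$a_dup, y))

  one <- best_puo2_feature(f["b_weak"], y)
  expect_equal(one$name, "b_weak")
  expect_error(best_puo2_feature(f[, 0], y), "no PuO2 features")
})
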