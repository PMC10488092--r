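# Small fixtures built in code, shared across test files.

# A minimal surgical timeline: one bypass run.
make_timeline <- function(surgery_end = 300L, runs = list(c(100L, 200L)),
                          start = 0L) {
  structure(list(surgery_start_s = as.integer(start),
                 surgery_end_s = as.integer(surgery_end),
                 cpb_runs = runs),
            class = "surgical_timeline")
}

# A clean 1 Hz waveform with constant channels; artifacts are edited in by
# individual tests.
make_waveform <- function(t = 0:299, puo2 = 45, flow = 5, temp = 36,
                          ecode = 0L) {
  data.frame(t_s = as.integer(t),
             puo2_mmHg = rep_len(puo2, length(t)),
             flow_ml_min = rep_len(flow, length(t)),
             temp_c = rep_len(temp, length(t)),
             error_code = rep_len(as.integer(ecode), length(t)))
}

# A tiny generated cohort for integration-flavoured tests.
small_cohort <- function(n = 8, seed = 11, delta = 10, ...) {
  generate_cohort(cohort_config(n_subjects = n, rng_seed = seed,
                                delta_mmHg = delta, ...))
}

# Fast model config for tests that only need structure, not accuracy.
fast_model <- function(seed = 1, B = 15) {
  model_config(n_estimators = B, rng_seed = seed)
}

# Independent brute-force oracles -------------------------------------------

# AUROC by direct enumeration of case-control pairs.
auroc_pairs <- function(values, y) {
  cases <- values[y == 1]; controls <- values[y == 0]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}

# Forward stepwise selection, re-fit from scratch with glm each step.
forward_select_oracle <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  retained <- character(0)
  repeat {
    remaining <- setdiff(names(X), retained)
    if (!length(remaining)) return(retained)
    ps <- sapply(remaining, function(f) {
      d <- cbind(data.frame(y = y), X[c(retained, f)])
      fit <- suppressWarnings(glm(y ~ ., data = d, family = binomial()))
      summary(fit)$coefficients[nrow(summary(fit)$coefficients), 4]
    })
    if (min(ps) >= alpha) return(retained)
    retained <- c(retained, remaining[which.min(ps)])
  }
}

# Exact McNemar p by full enumeration of the 2^(b+c) discordant outcomes
# under the symmetric null, two-sided by doubling the smaller tail.
mcnemar_enumerate <- function(b, cc) {
  n <- b + cc
  if (n == 0) return(1)
  probs <- sapply(0:n, function(k) choose(n, k) * 0.5^n)
  min(1, 2 * sum(probs[seq_len(min(b, cc) + 1)]))
}
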