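#' @keywords internal
"_PACKAGE"

# Deterministic derivation of stream seeds from one global seed. All derived
# seeds stay below 2^31 - 1 so they are valid R integer seeds.
derive_seed <- function(base, salt) {
  stopifnot(is.numeric(base), is.numeric(salt), length(base) == 1L)
  as.integer((as.double(base) * 48271 + as.double(salt) * 16807 + 12345) %%
               2147483647)
}

# Trailing mean of x over a window of `window` samples (including the current
# one), ignoring NAs. Early samples use the truncated (expanding) window.
# Returns NA where the window holds no finite values.
trailing_mean <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  window <- max(1L, as.integer(window))
  ok <- !is.na(x)
  cs <- cumsum(ifelse(ok, x, 0))
  cn <- cumsum(as.integer(ok))
  lag <- pmax(seq_len(n) - window, 0L)
  s <- cs - c(0, cs)[lag + 1L]
  k <- cn - c(0, cn)[lag + 1L]
  out <- s / k
  out[k == 0L] <- NA_real_
  out
}

# Dilate a logical vector by `guard` positions on each side (1 Hz grid).
dilate_logical <- function(x, guard) {
  guard <- as.integer(guard)
  if (guard <= 0L || !any(x)) return(x)
  n <- length(x)
  out <- logical(n)
  idx <- which(x)
  for (i in idx) {
    lo <- max(1L, i - guard)
    hi <- min(n, i + guard)
    out[lo:hi] <- TRUE
  }
  out
}

# Truncated normal draw by rejection (vectorized); falls back to the bound.
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  tries <- 0L
  while (length(bad) > 0L && tries < 100L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
    tries <- tries + 1L
  }
  pmin(pmax(x, lower), upper)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
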