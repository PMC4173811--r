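# Shared helpers: independent reference implementations used as oracles.

# Run every test file to completion even when several acceptance
# expectations are red; the default cap would end the run early.
options(testthat.progress.max_fails = 1000)

# Straightforward loop-and-lm DFA, independent of the package's
# vectorised path: global mean removal, cumulative sum, non-overlapping
# windows from the start, per-window linear fit, pooled RMS residual.
reference_dfa <- function(x, windows) {
  prof <- cumsum(x - mean(x))
  vapply(windows, function(n) {
    k <- length(prof) %/% n
    res2 <- 0
    for (w in seq_len(k)) {
      seg <- prof[((w - 1) * n + 1):(w * n)]
      t <- seq_len(n)
      fit <- lm(seg ~ t)
      res2 <- res2 + sum(residuals(fit)^2)
    }
    sqrt(res2 / (k * n))
  }, numeric(1))
}

# Pseudo-log-likelihood of a straight line on a scaled fluctuation plot,
# written directly from its definition (independent of the C++ path).
reference_linear_loglik <- function(a1, a2, x, y) {
  f <- abs(a1 + a2 * x)
  if (sum(f) == 0) return(-Inf)
  p <- f / sum(f)
  sum(ifelse(y > 0, y * log(p), 0))
}

# A synthetic exactly-collinear fluctuation plot with given slope.
collinear_plot <- function(slope, n_points = 20, intercept = -1) {
  sizes <- round(10^seq(log10(8), log10(2000), length.out = n_points))
  sizes <- unique(sizes)
  structure(list(window_sizes = sizes,
                 fluctuations = 10^(intercept + slope * log10(sizes)),
                 log_sizes = log10(sizes),
                 log_fluctuations = intercept + slope * log10(sizes),
                 n = NA_integer_, degenerate = FALSE),
            class = "dfa_plot")
}
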