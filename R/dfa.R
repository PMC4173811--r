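# Detrended fluctuation analysis: window schemes, fluctuation plots and
# the scaling exponent. Linearity of the fluctuation plot is judged
# separately by ML-DFA (see mldfa.R).

#' Logarithmically spaced DFA window scheme
#'
#' Builds the set of window (box) sizes used by DFA: `n_windows` sizes
#' log-spaced between `min_window` and `floor(n_samples / 10)`. Duplicate
#' sizes after rounding are dropped, so the scheme may hold fewer than
#' `n_windows` distinct sizes.
#'
#' @param n_samples Length of the series to be analysed.
#' @param min_window Smallest window size in samples (>= 4). Use 8 for
#'   simulated data with no characteristic scale; for oscillatory
#'   physiological data use about one second of samples.
#' @param n_windows Number of window sizes before deduplication (default 20).
#' @return Integer vector of strictly increasing window sizes.
#' @examples
#' make_windows(2^16, 8)
#' @export
make_windows <- function(n_samples, min_window = 8L, n_windows = 20L) {
  n_samples <- as.integer(n_samples)
  min_window <- as.integer(min_window)
  if (min_window < 4L) stop("min_window must be >= 4")
  max_window <- n_samples %/% 10L
  if (max_window < min_window)
    stop("series too short: max window ", max_window, " < min window ", min_window)
  sizes <- unique(as.integer(round(10^seq(log10(min_window), log10(max_window),
                                          length.out = n_windows))))
  sizes[sizes >= min_window & sizes <= max_window]
}

#' DFA profile (integrated series)
#'
#' Cumulative sum of the mean-centred series: global mean removal, then
#' integration. Per-window linear detrending is applied afterwards by
#' [dfa_fluctuations()].
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
dfa_profile <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 samples")
  cumsum(x - mean(x))
}

#' DFA fluctuation plot
#'
#' For each window size `n` the profile is split into `floor(N/n)`
#' non-overlapping windows from the start of the series (any trailing
#' partial window is discarded), each window is detrended by linear least
#' squares, and `F(n)` is the root mean square of the residuals pooled
#' over all covered points.
#'
#' @param x Numeric vector, the series to analyse (not the profile).
#' @param windows Integer vector of window sizes, e.g. from
#'   [make_windows()]; defaults to `make_windows(length(x), min_window)`.
#' @param min_window Passed to [make_windows()] when `windows` is NULL.
#' @param n_windows Passed to [make_windows()] when `windows` is NULL.
#' @return An object of class `"dfa_plot"`: a list with `window_sizes`,
#'   `fluctuations`, `log_sizes`, `log_fluctuations` (base-10 logs) and
#'   `n` (series length). Degenerate plots (some `F(n) == 0`) carry
#'   `degenerate = TRUE` and `log_fluctuations` of `-Inf` at those sizes.
#' @examples
#' fp <- dfa_fluctuations(rnorm(4096), min_window = 8)
#' plot(fp)
#' @export
dfa_fluctuations <- function(x, windows = NULL, min_window = 8L, n_windows = 20L) {
  x <- as.numeric(x)
  if (is.null(windows)) windows <- make_windows(length(x), min_window, n_windows)
  windows <- as.integer(windows)
  if (any(windows < 2L) || any(windows > length(x)))
    stop("window sizes must lie in [2, length(x)]")
  prof <- dfa_profile(x)
  N <- length(prof)
  fl <- vapply(windows, function(n) {
    k <- N %/% n
    Y <- matrix(prof[seq_len(k * n)], nrow = n, ncol = k)
    t0 <- seq_len(n) - (n + 1) / 2           # centred time index
    denom <- sum(t0^2)
    cm <- colMeans(Y)
    Yc <- Y - rep(cm, each = n)
    slopes <- as.numeric(crossprod(t0, Yc)) / denom
    res <- Yc - outer(t0, slopes)
    sqrt(mean(res^2))
  }, numeric(1))
  structure(list(window_sizes = windows,
                 fluctuations = fl,
                 log_sizes = log10(windows),
                 log_fluctuations = log10(fl),
                 n = N,
                 degenerate = any(fl == 0)),
            class = "dfa_plot")
}

#' DFA scaling exponent
#'
#' Ordinary least-squares slope of `log10 F(n)` against `log10 n` over all
#' window sizes of the plot. An exponent near 0.5 indicates an uncorrelated
#' (white) series, 0.5 < H < 1 long-range temporal correlations, H = 1.5
#' Brownian noise.
#'
#' @param plot A `"dfa_plot"` from [dfa_fluctuations()].
#' @return The exponent (slope), a single number.
#' @export
dfa_exponent <- function(plot) {
  stopifnot(inherits(plot, "dfa_plot"))
  if (length(plot$window_sizes) < 3L) stop("need at least 3 points for the exponent")
  if (plot$degenerate)
    stop("degenerate fluctuation plot: zero fluctuation at some window size ",
         "(fully synchronized input, no fluctuations)")
  as.numeric(coef(lm(plot$log_fluctuations ~ plot$log_sizes))[2L])
}

#' Detrended fluctuation analysis of a time series
#'
#' Convenience wrapper: builds the window scheme, computes the fluctuation
#' plot and the exponent, and returns a classed object with print/plot
#' methods. For a validated exponent use [mldfa()] on the returned object.
#'
#' @inheritParams dfa_fluctuations
#' @return Object of class `"dfa"`: list with `plot` (the `"dfa_plot"`),
#'   `exponent`, `min_window`, `n`.
#' @examples
#' d <- dfa(rnorm(2^14))
#' d$exponent   # about 0.5
#' @export
dfa <- function(x, windows = NULL, min_window = 8L, n_windows = 20L) {
  fp <- dfa_fluctuations(x, windows, min_window, n_windows)
  expo <- if (fp$degenerate) NA_real_ else dfa_exponent(fp)
  structure(list(plot = fp, exponent = expo,
                 min_window = min(fp$window_sizes), n = fp$n),
            class = "dfa")
}

#' @export
print.dfa <- function(x, ...) {
  cat("Detrended fluctuation analysis\n")
  cat("  series length:", x$n, "  window sizes:",
      length(x$plot$window_sizes),
      sprintf("(%d..%d)", min(x$plot$window_sizes), max(x$plot$window_sizes)), "\n")
  if (is.na(x$exponent)) {
    cat("  degenerate fluctuation plot (zero fluctuations); no exponent\n")
  } else {
    cat(sprintf("  exponent H = %.3f\n", x$exponent))
  }
  invisible(x)
}

#' @export
coef.dfa <- function(object, ...) c(H = object$exponent)

#' @export
plot.dfa_plot <- function(x, ...) {
  plot(x$log_sizes, x$log_fluctuations,
       xlab = expression(log[10] ~ "window size"),
       ylab = expression(log[10] ~ "F(n)"),
       main = "DFA fluctuation plot", pch = 19, ...)
  if (!x$degenerate) {
    fit <- lm(x$log_fluctuations ~ x$log_sizes)
    abline(fit, col = "grey40", lty = 2)
    legend("topleft", bty = "n",
           legend = sprintf("slope = %.3f", coef(fit)[2L]))
  }
  invisible(x)
}

#' @export
plot.dfa <- function(x, ...) plot(x$plot, ...)

#' Write / read a fluctuation plot as CSV
#'
#' Two columns, `window_size` and `fluctuation`; one row per window size.
#'
#' @param plot A `"dfa_plot"`.
#' @param path File path.
#' @return `write_dfa_plot` returns `path` invisibly; `read_dfa_plot`
#'   returns a `"dfa_plot"`.
#' @export
write_dfa_plot <- function(plot, path) {
  stopifnot(inherits(plot, "dfa_plot"))
  write.csv(data.frame(window_size = plot$window_sizes,
                       fluctuation = plot$fluctuations),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dfa_plot
#' @export
read_dfa_plot <- function(path) {
  d <- read.csv(path)
  stopifnot(all(c("window_size", "fluctuation") %in% names(d)))
  structure(list(window_sizes = as.integer(d$window_size),
                 fluctuations = as.numeric(d$fluctuation),
                 log_sizes = log10(d$window_size),
                 log_fluctuations = log10(d$fluctuation),
                 n = NA_integer_,
                 degenerate = any(d$fluctuation == 0)),
            class = "dfa_plot")
}
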