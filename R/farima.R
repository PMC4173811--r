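# FARIMA(p, d, q) generation with p, q in {0, 1}. The fractionally
# integrated core is fractional Gaussian noise in the ARFIMA sense:
# a stationary Gaussian series with autocovariances
#   rho(k) = rho(k-1) * (k - 1 + d) / (k - d),  gamma(0) = G(1-2d)/G(1-d)^2,
# so that DFA of a FARIMA(0, d, 0) series scales with exponent d + 1/2.

#' Autocovariances of fractionally integrated noise
#'
#' Autocovariance sequence of ARFIMA(0, d, 0) with unit innovation
#' variance, lags `0 .. max_lag`. Satisfies
#' `rho(1) = d / (1 - d)`.
#'
#' @param d Fractional differencing parameter, `|d| < 0.5`.
#' @param max_lag Largest lag required.
#' @return Numeric vector of length `max_lag + 1`.
#' @export
farima_acvf <- function(d, max_lag) {
  stopifnot(abs(d) < 0.5)
  if (d == 0) return(c(1, numeric(max_lag)))
  g0 <- gamma(1 - 2 * d) / gamma(1 - d)^2
  k <- seq_len(max_lag)
  rho <- cumprod((k - 1 + d) / (k - d))
  g0 * c(1, rho)
}

# Exact sampler via circulant embedding (Davies-Harte). O(n log n),
# exact in distribution for the given autocovariance sequence.
circulant_fgn <- function(n, d) {
  m <- n
  g <- farima_acvf(d, m)
  row <- c(g, rev(g[2:m]))                    # length 2m circulant row
  lam <- Re(fft(row))
  tol <- 1e-8 * max(lam)
  if (any(lam < -tol))
    stop("circulant embedding not nonnegative definite for d = ", d)
  lam[lam < 0] <- 0
  z <- rnorm(2 * m)
  V <- complex(length.out = 2 * m)
  V[1] <- sqrt(lam[1]) * z[1]
  V[m + 1] <- sqrt(lam[m + 1]) * z[2]
  idx <- seq_len(m - 1)
  V[1 + idx] <- sqrt(lam[1 + idx] / 2) * complex(real = z[2 * idx + 1],
                                                 imaginary = z[2 * idx + 2])
  V[2 * m + 1 - idx] <- Conj(V[1 + idx])
  x <- Re(fft(V)) / sqrt(2 * m)
  x[seq_len(n)]
}

#' Generate a FARIMA(p, d, q) series
#'
#' Fractionally integrated Gaussian noise with optional AR(1) and MA(1)
#' parts. The fractional core is sampled exactly from its autocovariance
#' sequence, either with Hosking's Durbin-Levinson recursion
#' (`method = "hosking"`, O(n^2), faithful to the classical algorithm) or
#' with circulant embedding (`method = "circulant"`, O(n log n), exact in
#' distribution and the default so that long series remain affordable).
#' The MA then AR filters are applied after fractional integration.
#'
#' @param n Series length.
#' @param d Fractional differencing parameter; `|d| < 0.5`. `d = H - 1/2`
#'   links it to a target DFA exponent `H`.
#' @param phi AR(1) coefficient, `|phi| < 1` (0 disables).
#' @param theta MA(1) coefficient, `|theta| < 1` (0 disables).
#' @param seed Optional integer seed.
#' @param method `"circulant"` (default) or `"hosking"`.
#' @return Numeric vector of length `n`, zero-mean.
#' @examples
#' x <- farima_generate(2^12, d = 0.2, seed = 1)
#' dfa(x)$exponent      # about 0.7
#' @export
farima_generate <- function(n, d, phi = 0, theta = 0, seed = NULL,
                            method = c("circulant", "hosking")) {
  method <- match.arg(method)
  if (!(abs(d) < 0.5)) stop("require |d| < 0.5")
  if (!(abs(phi) < 1)) stop("require |phi| < 1")
  if (!(abs(theta) < 1)) stop("require |theta| < 1")
  n <- as.integer(n)
  stopifnot(n >= 2L)
  x <- with_seed(seed, {
    core <- if (method == "hosking") {
      hosking_sim(farima_acvf(d, n - 1L), rnorm(n))
    } else {
      circulant_fgn(n, d)
    }
    core
  })
  if (theta != 0) {
    w <- x + theta * c(0, x[-n])
  } else w <- x
  if (phi != 0) {
    w <- as.numeric(stats::filter(w, phi, method = "recursive"))
  }
  w - mean(w)
}
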