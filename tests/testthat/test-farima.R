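# FARIMA generation (both samplers) and surrogate-pair construction.

test_that("parameter bounds are enforced", {
  expect_error(farima_generate(100, d = 0.6), "d")
  expect_error(farima_generate(100, d = 0.2, phi = 1.2), "phi")
  expect_error(farima_generate(100, d = 0.2, theta = -1), "theta")
})

test_that("d = 0 is white noise", {
  x <- farima_generate(2^16, d = 0, seed = 3)
  expect_lt(abs(acf(x, plot = FALSE)$acf[2]), 0.02)
  xh <- farima_generate(2^12, d = 0, seed = 3, method = "hosking")
  expect_lt(abs(acf(xh, plot = FALSE)$acf[2]), 0.05)
})

test_that("lag-1 autocorrelation approaches d/(1-d) for both samplers", {
  for (d in c(0.1, 0.3)) {
    xc <- farima_generate(2^16, d = d, seed = 17 + round(10 * d))
    expect_equal(acf(xc, plot = FALSE)$acf[2], d / (1 - d), tolerance = 0.03)
  }
  xh <- farima_generate(2^13, d = 0.25, seed = 5, method = "hosking")
  expect_equal(acf(xh, plot = FALSE)$acf[2], 0.25 / 0.75, tolerance = 0.05)
})

test_that("the two samplers agree in scaling: DFA exponent near d + 1/2", {
  xc <- farima_generate(2^16, d = 0.2, seed = 8)
  expect_equal(dfa(xc)$exponent, 0.7, tolerance = 0.05)
  xh <- farima_generate(2^13, d = 0.2, seed = 8, method = "hosking")
  expect_equal(dfa(xh)$exponent, 0.7, tolerance = 0.1)
})

test_that("theoretical autocovariances match sample moments", {
  g <- farima_acvf(0.3, 5)
  expect_equal(g[2] / g[1], 0.3 / 0.7, tolerance = 1e-12)
  # recursion rho(k) = rho(k-1)(k-1+d)/(k-d)
  expect_equal(g[3] / g[2], (1 + 0.3) / (2 - 0.3), tolerance = 1e-12)
  x <- farima_generate(2^16, d = 0.3, seed = 12)
  expect_equal(var(x), g[1], tolerance = 0.15 * g[1])
})

test_that("AR and MA parts shape the short-range structure", {
  x_ar <- farima_generate(2^15, d = 0, phi = 0.6, seed = 4)
  expect_equal(acf(x_ar, plot = FALSE)$acf[2], 0.6, tolerance = 0.03)
  x_ma <- farima_generate(2^15, d = 0, theta = 0.5, seed = 4)
  expect_equal(acf(x_ma, plot = FALSE)$acf[2], 0.5 / (1 + 0.25),
               tolerance = 0.03)
})

test_that("surrogate pairs are seed-reproducible and respect the noise switch", {
  a <- surrogate_pair(4096, d = 0.25, seed = 9)
  b <- surrogate_pair(4096, d = 0.25, seed = 9)
  expect_identical(a$x1, b$x1)
  noisy <- surrogate_pair(4096, d = 0.25, seed = 9, noise_sigma = 0.5)
  expect_identical(noisy$x2, a$x2)           # noise goes on x1 only
  expect_false(identical(noisy$x1, a$x1))
  expect_equal(sd(noisy$x1 - a$x1), 0.5, tolerance = 0.05)
})

test_that("recovered exponent is invariant to the sign of the FARIMA core (pair swap)", {
  sp <- surrogate_pair(2^14, d = 0.3, seed = 13)
  # negating X swaps the roles of x1 and x2
  h12 <- dfa(rate_of_change(phase_difference(sp$x1, sp$x2)),
             min_window = 600)$exponent
  h21 <- dfa(rate_of_change(phase_difference(sp$x2, sp$x1)),
             min_window = 600)$exponent
  expect_equal(h12, h21, tolerance = 1e-10)
})
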