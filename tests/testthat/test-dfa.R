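# DFA window schemes, fluctuation plots and exponents.

test_that("window schemes are log-spaced with max N/10", {
  w <- make_windows(4194304, 600)
  expect_equal(max(w), 419430)
  expect_equal(min(w), 600)
  expect_true(all(diff(w) > 0))
  w2 <- make_windows(6100, 8)
  expect_equal(max(w2), 610)
  expect_lte(length(w2), 20)
  expect_error(make_windows(50, 8), "too short")
  expect_error(make_windows(1000, 3), "min_window")
})

test_that("the profile is the integrated mean-centred series", {
  expect_equal(dfa_profile(rep(3, 50)), rep(0, 50))
  x <- rnorm(500)
  expect_equal(dfa_profile(-x), -dfa_profile(x))
  expect_equal(dfa_profile(x)[500], 0, tolerance = 1e-9)
})

test_that("exact power-law plots return their slope to numerical precision", {
  fp <- collinear_plot(slope = 0.7)
  expect_equal(dfa_exponent(fp), 0.7, tolerance = 1e-10)
  # scale invariance: doubling all F shifts the intercept only
  fp2 <- fp
  fp2$fluctuations <- 2 * fp$fluctuations
  fp2$log_fluctuations <- log10(fp2$fluctuations)
  expect_equal(dfa_exponent(fp2), dfa_exponent(fp), tolerance = 1e-12)
})

test_that("white and Brownian noise give their textbook exponents", {
  set.seed(5)
  hs <- replicate(4, {
    x <- rnorm(2^16)
    c(dfa(x)$exponent, dfa(cumsum(x))$exponent)
  })
  expect_equal(mean(hs[1, ]), 0.5, tolerance = 0.05)
  expect_equal(mean(hs[2, ]), 1.5, tolerance = 0.05)
})

test_that("fluctuations match an independent reference implementation within 1%", {
  set.seed(9)
  for (i in 1:10) {
    x <- switch(1 + i %% 3,
                rnorm(3000),
                cumsum(rnorm(3000)),
                arima.sim(list(ar = 0.7), 3000))
    w <- make_windows(length(x), 8, 12)
    got <- dfa_fluctuations(x, windows = w)$fluctuations
    ref <- reference_dfa(as.numeric(x), w)
    expect_equal(got, ref, tolerance = 0.01)
  }
})

test_that("degenerate plots are flagged and refuse an exponent", {
  fp <- dfa_fluctuations(rep(0, 1000), min_window = 8)
  expect_true(fp$degenerate)
  expect_error(dfa_exponent(fp), "degenerate")
  expect_true(is.na(dfa(rep(0, 1000))$exponent))
})

test_that("dfa objects print, summarise and round-trip through CSV", {
  d <- dfa(rnorm(4096))
  expect_output(print(d), "exponent")
  expect_equal(unname(coef(d)), d$exponent)
  path <- tempfile(fileext = ".csv")
  write_dfa_plot(d$plot, path)
  back <- read_dfa_plot(path)
  expect_equal(back$fluctuations, d$plot$fluctuations, tolerance = 1e-8)
  expect_equal(back$window_sizes, d$plot$window_sizes)
})
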