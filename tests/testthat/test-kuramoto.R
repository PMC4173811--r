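# Kuramoto model: critical coupling, order parameter, limiting
# behaviours and sweep structure.

test_that("critical coupling closed form", {
  expect_equal(round(critical_coupling(15), 2), 23.94)
  expect_equal(critical_coupling(30), 2 * critical_coupling(15))
  expect_equal(critical_coupling(sqrt(pi / 2)), 2)
  expect_error(critical_coupling(-1))
})

test_that("uncoupled noiseless oscillators advance exactly at omega*dt", {
  sim <- kuramoto_simulate(0, n_osc = 5, noise_sd = 0, n_steps = 200,
                           dt = 1e-3, seed = 3)
  steps <- t(diff(t(sim$phases)))
  for (i in 1:5)
    expect_equal(unname(steps[i, ]), rep(sim$omega[i] * 1e-3, 199),
                 tolerance = 1e-12)
})

test_that("strong noiseless coupling entrains the population (r -> 1)", {
  K <- 10 * critical_coupling(15)
  sim <- kuramoto_simulate(K, n_osc = 50, noise_sd = 0, n_steps = 3000,
                           seed = 4)
  r <- order_parameter(sim$phases)$r
  expect_gt(tail(r, 1), 0.99)
})

test_that("two identical uncoupled oscillators keep a constant phase difference", {
  sim <- kuramoto_simulate(0, n_osc = 2, noise_sd = 0, n_steps = 500,
                           seed = 6, omega = c(140, 140))
  d <- sim$phases[1, ] - sim$phases[2, ]
  expect_equal(max(abs(d - d[1])), 0, tolerance = 1e-12)
})

test_that("order parameter closed forms and bounds", {
  expect_equal(order_parameter(matrix(rep(0.7, 12), ncol = 1))$mean_r, 1)
  N <- 8
  expect_equal(order_parameter(matrix(2 * pi * (1:N) / N, ncol = 1))$mean_r,
               0, tolerance = 1e-12)
  expect_equal(order_parameter(matrix(c(0, pi), ncol = 1))$mean_r, 0,
               tolerance = 1e-12)
  sim <- kuramoto_simulate(5, n_osc = 20, n_steps = 400, seed = 8)
  r <- order_parameter(sim$phases)$r
  expect_true(all(r >= 0 & r <= 1))
})

test_that("mean order parameter is non-decreasing in K on a coarse grid", {
  Ks <- c(0, 8, 16, 32, 64)
  rbar <- sapply(Ks, function(K) {
    mean(sapply(1:5, function(s)
      order_parameter(kuramoto_simulate(K, n_osc = 40, n_steps = 1500,
                                        seed = 100 * s)$phases,
                      discard_frac = 0.3)$mean_r))
  })
  sds <- 0.05
  expect_true(all(diff(rbar) > -2 * sds))
})

test_that("kuramoto sweeps carry delta_Kr aligned to the right endpoint", {
  sw <- kuramoto_sweep(c(0, 40), n_osc = 25, n_steps = 1200,
                       pair_subset = 8, seed = 5)
  expect_true(is.na(sw$delta_Kr[1]))
  expect_equal(sw$delta_Kr[2],
               sw$control[2] * sw$mean_order_r[2] -
               sw$control[1] * sw$mean_order_r[1])
  expect_equal(sw$validity_fraction * sw$n_pairs_analyzed, sw$n_valid)
})
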