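# Delayed network model: delays, disruptions, randomization, the
# synthetic connectome and consistency with the mean-field model.

test_that("delays scale distances to the requested mean", {
  L <- matrix(5, 4, 4); diag(L) <- 0
  D <- delays_from_distances(L, 11)
  off <- D$values[row(D$values) != col(D$values)]
  expect_true(all(off == 11))
  # scale-free in the distance units
  D2 <- delays_from_distances(2 * L, 11)
  expect_equal(D2$values, D$values)
  # <D> = 0 removes all delays
  expect_true(all(delays_from_distances(L, 0)$step_counts == 0))
  # mean over connected pairs equals <D> exactly before rounding
  set.seed(2)
  M <- matrix(runif(36, 1, 9), 6); M <- (M + t(M)) / 2; diag(M) <- 0
  D3 <- delays_from_distances(M, 11)
  expect_equal(mean(D3$values[row(M) != col(M) & M > 0]), 11,
               tolerance = 1e-12)
  expect_error(delays_from_distances(matrix(0, 3, 3), 11), "zero")
})

test_that("two strongly coupled identical nodes synchronise fully", {
  C <- matrix(c(0, 1, 1, 0), 2)
  sim <- network_simulate(C, coupling = 50, mean_delay = 0, noise_sd = 0,
                          n_steps = 4000, seed = 3, omega = c(377, 377))
  d <- sim$phases[1, ] - sim$phases[2, ]
  # phase difference converges to 0 modulo 2*pi
  expect_lt(abs(sin(tail(d, 1) / 2)), 1e-6)
})

test_that("zero connectivity leaves free noisy rotators regardless of K", {
  C0 <- matrix(0, 5, 5)
  a <- network_simulate(C0, coupling = 0, mean_delay = 0, n_steps = 300,
                        seed = 9)
  b <- network_simulate(C0, coupling = 25, mean_delay = 0, n_steps = 300,
                        seed = 9)
  expect_equal(a$phases, b$phases)
})

test_that("hemisphere disconnection zeroes exactly the cross-hemisphere entries", {
  set.seed(4)
  C <- matrix(runif(64), 8); diag(C) <- 0
  hemi <- rep(c("L", "R"), each = 4)
  Cd <- disconnect_hemispheres(C, hemi)
  same <- outer(hemi, hemi, `==`)
  expect_identical(Cd[same], C[same])          # within untouched, exactly
  expect_true(all(Cd[!same] == 0))
  expect_equal(sum(Cd != 0), sum(C != 0 & same))
  # block-diagonal input is a fixed point
  Cbd <- C; Cbd[!same] <- 0
  expect_identical(disconnect_hemispheres(Cbd, hemi), Cbd)
  # all-cross input maps to the zero matrix
  Cx <- C; Cx[same] <- 0
  expect_true(all(disconnect_hemispheres(Cx, hemi) == 0))
  expect_error(disconnect_hemispheres(C, rep("L", 8)), "two hemisphere")
})

test_that("randomization preserves per-node out-degree and weight multisets exactly", {
  cx <- synthetic_connectome(seed = 2)
  for (s in 1:3) {
    R <- randomize_connectivity(cx$C, seed = s)
    expect_true(all(diag(R) == 0))
    for (i in 1:66) {
      expect_equal(sort(R[i, R[i, ] > 0]), sort(cx$C[i, cx$C[i, ] > 0]),
                   tolerance = 1e-14)
    }
  }
})

test_that("randomization destroys planted block structure", {
  cx <- synthetic_connectome(seed = 6)
  clustered <- cx$clusters != "individual"
  within <- outer(cx$clusters, cx$clusters, `==`) &
    outer(clustered, clustered, `&`)
  orig_share <- sum(cx$C_raw[within]) / sum(cx$C_raw)
  # expected within-cluster weight share under random stub pairing (each
  # edge keeps its source node, the partner stub is uniform over stubs):
  # sum_c (weight share of cluster c) * (stub-count share of cluster c)
  nz <- which(cx$C_raw != 0, arr.ind = TRUE)
  sn <- cx$clusters[nz[, 1]]
  w <- cx$C_raw[nz]
  expected_share <- sum(sapply(unique(cx$clusters[clustered]), function(c)
    sum(w[sn == c]) / sum(w) * sum(sn == c) / length(w)))
  shares <- sapply(1:10, function(s) {
    R <- randomize_connectivity(cx$C_raw, seed = 100 + s)
    sum(R[within]) / sum(R)
  })
  expect_gt(orig_share, 0.8)                   # structure is strongly planted
  expect_lt(mean(shares), orig_share / 2)      # planted blocks destroyed
  expect_equal(mean(shares), expected_share, tolerance = 0.1)
})

test_that("cluster summaries report row sums and degrees per label", {
  C <- matrix(1 / 3, 4, 4); diag(C) <- 0
  s <- cluster_summary(C, rep("all", 4))
  expect_equal(s$mean_weight_per_node, 1)
  expect_equal(s$mean_degree, 3)
  C2 <- rbind(cbind(C, matrix(0, 4, 2)), matrix(0, 2, 6))
  s2 <- cluster_summary(C2, c(rep("core", 4), rep("isolated", 2)))
  expect_equal(s2$mean_weight_per_node[s2$cluster == "isolated"], 0)
  expect_equal(s2$mean_degree[s2$cluster == "isolated"], 0)
})

test_that("the synthetic connectome honours its construction contract", {
  for (s in c(1, 7)) {
    cx <- synthetic_connectome(seed = s)
    rs <- rowSums(cx$C)
    expect_true(all(abs(rs[rowSums(cx$C_raw) > 0] - 1) < 1e-12))
    expect_true(all(diag(cx$C) == 0))
    expect_equal(max(abs(cx$L - t(cx$L))), 0, tolerance = 1e-9)
    cs <- cluster_summary(cx$C_raw, cx$clusters)
    w4 <- cs$mean_weight_per_node[cs$cluster == "cluster4"]
    expect_true(all(w4 > cs$mean_weight_per_node[cs$cluster != "cluster4"]))
    # hemisphere disconnection removes every homologous link
    Cd <- disconnect_hemispheres(cx$C, cx$hemisphere)
    for (i in 27:33) expect_equal(Cd[i, 67 - i], 0)
    # cluster sizes as planted
    expect_equal(unname(table(cx$clusters)[paste0("cluster", 1:6)]),
                 c(11L, 5L, 8L, 14L, 5L, 11L), ignore_attr = TRUE)
    expect_equal(sum(cx$clusters == "individual"), 12)
  }
})

test_that("with zero delays and uniform full coupling the network matches the mean-field model", {
  N <- 30
  C <- matrix(1 / (N - 1), N, N); diag(C) <- 0
  K <- 6
  # the network drive K * sum_j C_ij sin(...) with rows summing to 1 equals
  # the mean-field (K/N') * sum_j sin(...) at K' = K * N/(N-1); with the
  # same seed both integrators consume the same random stream, so the
  # trajectories (and hence every order-parameter statistic) coincide
  r_net <- numeric(5); r_mf <- numeric(5)
  for (s in 1:5) {
    net <- network_simulate(C, coupling = K, mean_delay = 0,
                            mean_freq_hz = 22, freq_sd = 3, noise_sd = 0.32,
                            n_steps = 1000, seed = 50 + s)
    mf <- kuramoto_simulate(K * N / (N - 1), n_osc = N, mean_freq_hz = 22,
                            freq_sd = 3, noise_sd = 0.32, n_steps = 1000,
                            seed = 50 + s)
    if (s == 1) expect_equal(net$phases, mf$phases, tolerance = 1e-10)
    r_net[s] <- order_parameter(net$phases, discard_frac = 0.3)$mean_r
    r_mf[s] <- order_parameter(mf$phases, discard_frac = 0.3)$mean_r
  }
  expect_lt(abs(mean(r_net) - mean(r_mf)),
            2 * sqrt(var(r_net) / 5 + var(r_mf) / 5) + 0.05)
})

test_that("network sweeps keep bookkeeping and expose per-pair matrices", {
  cx <- synthetic_connectome(seed = 3)
  sw <- network_sweep(c(0, 10), connectome = cx, n_steps = 3000,
                      pair_subset = 12, seed = 2, detail = TRUE)
  expect_equal(sw$validity_fraction * sw$n_pairs_analyzed, sw$n_valid)
  det <- attr(sw, "detail")[["0"]]
  M <- pair_exponent_matrix(det, 66)
  expect_equal(M, t(M))
  v <- det$valid & !is.na(det$exponent)
  expect_equal(sum(!is.na(M[upper.tri(M)])), sum(v))
})

test_that("delays exceeding the horizon raise a configuration error", {
  C <- matrix(c(0, 1, 1, 0), 2)
  L <- matrix(c(0, 5, 5, 0), 2)
  expect_error(network_simulate(C, L, coupling = 1, mean_delay = 500,
                                n_steps = 300, seed = 1),
               "configuration error")
})
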