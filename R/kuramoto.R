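# Noisy mean-field Kuramoto model: simulation, order parameter, the
# critical-coupling constant and the coupling sweep. The model yields
# phases directly, so the pipeline skips the analytic-signal step.

#' Critical coupling of the infinite Kuramoto model
#'
#' `Kc = 2 / (pi * g(0))` for a unimodal symmetric natural-frequency
#' density `g`; for the zero-centred normal density with standard
#' deviation `freq_sd` this is `2 * freq_sd * sqrt(2/pi)` (about 23.93
#' for `freq_sd = 15`).
#'
#' @param freq_sd Standard deviation of the natural-frequency
#'   distribution (radian-rate units).
#' @return The critical coupling, a single number.
#' @examples
#' critical_coupling(15)
#' @export
critical_coupling <- function(freq_sd) {
  stopifnot(freq_sd > 0)
  2 * freq_sd * sqrt(2 / pi)
}

#' Simulate the noisy mean-field Kuramoto model
#'
#' Euler-Maruyama integration of
#' `dphi_i = (omega_i + (K/N) sum_j sin(phi_j - phi_i)) dt + noise`,
#' with natural frequencies drawn once per seed from a normal law
#' centred at `2 * pi * mean_freq_hz` rad/s with SD `freq_sd`, and
#' per-step noise increments of variance `noise_sd^2 * dt` (the
#' continuous process has covariance `noise_sd^2 / T`, `T` = 1 s).
#' The coupling term is evaluated through the mean field
#' `r e^{i psi} = mean(e^{i phi_j})`, which is exact for uniform
#' all-to-all coupling. Returned phases are unwrapped by construction.
#'
#' @param coupling Coupling strength `K`.
#' @param n_osc Number of oscillators `N` (default 200).
#' @param mean_freq_hz Mean natural frequency in Hz (default 22, the
#'   beta band).
#' @param freq_sd SD of natural frequencies in radian-rate units
#'   (default 15).
#' @param noise_sd Noise SD in radians (default 0.32).
#' @param dt Integration step in seconds (default 1e-3).
#' @param n_steps Number of recorded steps (default 6100).
#' @param seed Optional integer seed.
#' @param omega Optional vector of natural frequencies (overrides the
#'   draw; length `n_osc`).
#' @return List with `phases` (`n_osc x n_steps` matrix of unwrapped
#'   radians), `omega`, and the call parameters.
#' @examples
#' sim <- kuramoto_simulate(coupling = 0, n_osc = 20, n_steps = 500, seed = 1)
#' dim(sim$phases)
#' @export
kuramoto_simulate <- function(coupling, n_osc = 200L, mean_freq_hz = 22,
                              freq_sd = 15, noise_sd = 0.32, dt = 1e-3,
                              n_steps = 6100L, seed = NULL, omega = NULL) {
  stopifnot(n_osc >= 2, dt > 0, noise_sd >= 0, n_steps >= 2)
  with_seed(seed, {
    if (is.null(omega)) omega <- rnorm(n_osc, 2 * pi * mean_freq_hz, freq_sd)
    stopifnot(length(omega) == n_osc)
    phases <- matrix(0, n_osc, n_steps)
    phi <- runif(n_osc, -pi, pi)
    phases[, 1] <- phi
    sig <- noise_sd * sqrt(dt)
    for (t in 2:n_steps) {
      z <- mean(complex(modulus = 1, argument = phi))
      # (K/N) sum_j sin(phi_j - phi_i) = K * r * sin(psi - phi_i)
      drive <- coupling * Mod(z) * sin(Arg(z) - phi)
      phi <- phi + dt * (omega + drive) +
        (if (sig > 0) rnorm(n_osc, 0, sig) else 0)
      phases[, t] <- phi
    }
    list(phases = phases, omega = omega, coupling = coupling,
         dt = dt, noise_sd = noise_sd, n_steps = n_steps)
  })
}

#' Kuramoto order parameter
#'
#' `r(t) e^{i psi(t)} = mean_j e^{i phi_j(t)}`: `r = 1` when all
#' oscillators are entrained, `r = 0` for uniformly spread phases.
#'
#' @param phases Matrix of phases, one oscillator per row, or a vector
#'   (one time point).
#' @param discard_frac Fraction of initial steps excluded from `mean_r`
#'   (default 0: use all steps).
#' @return List with `r` (per-step series) and `mean_r` (mean over the
#'   post-transient steps).
#' @examples
#' order_parameter(matrix(rep(1, 10), 10, 1))$mean_r   # 1
#' @export
order_parameter <- function(phases, discard_frac = 0) {
  if (is.vector(phases)) phases <- matrix(phases, ncol = 1)
  r <- sqrt(colMeans(cos(phases))^2 + colMeans(sin(phases))^2)
  keep <- seq.int(floor(discard_frac * length(r)) + 1L, length(r))
  list(r = r, mean_r = mean(r[keep]))
}

#' Coupling sweep of the noisy Kuramoto model
#'
#' For each coupling value (and each of `n_seeds` replicate
#' simulations): integrate the model, discard the initial transient,
#' compute the mean order parameter, and run DFA + ML-DFA on the rate of
#' change of the phase difference of every analysed oscillator pair
#' (direct phase differences; no analytic-signal step). Pair results are
#' pooled across seeds per coupling. `delta_Kr` is the first difference
#' of `K * mean_r` along the ascending coupling grid, aligned to the
#' right endpoint; its peak marks the coupling of maximal
#' synchronization flux.
#'
#' @param couplings Ascending vector of coupling values.
#' @param n_osc,mean_freq_hz,freq_sd,noise_sd,dt,n_steps As in
#'   [kuramoto_simulate()].
#' @param pair_subset Pairs analysed per simulation (default 2000;
#'   seeded random subset when fewer than all `choose(N, 2)` pairs).
#' @param n_seeds Replicate simulations per coupling (default 1).
#' @param seed Integer root seed.
#' @param discard_frac Initial fraction of steps dropped before
#'   analysis (default 0.1).
#' @param min_window,n_windows DFA window scheme (defaults 8 and 20).
#' @return Data frame of class `"phasecrit_sweep"`, one row per
#'   coupling: `control` (K), `mean_exponent`, `sd_exponent`,
#'   `validity_fraction`, `mean_order_r`, `delta_Kr`,
#'   `n_pairs_analyzed`, `n_valid`.
#' @examples
#' \donttest{
#' sw <- kuramoto_sweep(c(0, 10), n_osc = 30, n_steps = 2000,
#'                      pair_subset = 20, seed = 1)
#' }
#' @export
kuramoto_sweep <- function(couplings, n_osc = 200L, mean_freq_hz = 22,
                           freq_sd = 15, noise_sd = 0.32, dt = 1e-3,
                           n_steps = 6100L, pair_subset = 2000L,
                           n_seeds = 1L, seed = 1L, discard_frac = 0.1,
                           min_window = 8L, n_windows = 20L) {
  stopifnot(!is.unsorted(couplings))
  # one natural-frequency realization per replicate, held fixed across
  # the whole coupling grid: each seed is one system swept through K
  omegas <- lapply(seq_len(n_seeds), function(s)
    with_seed(child_seed(seed, 900000L + s),
              rnorm(n_osc, 2 * pi * mean_freq_hz, freq_sd)))
  rows <- lapply(seq_along(couplings), function(ki) {
    K <- couplings[ki]
    pr_all <- list(); r_all <- numeric(n_seeds)
    for (s in seq_len(n_seeds)) {
      cs <- child_seed(seed, ki * 131L + s)
      sim <- kuramoto_simulate(K, n_osc = n_osc, mean_freq_hz = mean_freq_hz,
                               freq_sd = freq_sd, noise_sd = noise_sd,
                               dt = dt, n_steps = n_steps, seed = cs,
                               omega = omegas[[s]])
      keep <- seq.int(floor(discard_frac * n_steps) + 1L, n_steps)
      ph <- sim$phases[, keep, drop = FALSE]
      r_all[s] <- order_parameter(ph)$mean_r
      pr_all[[s]] <- pair_pipeline(ph, pair_subset = pair_subset,
                                   seed = child_seed(cs, 7L),
                                   min_window = min_window,
                                   n_windows = n_windows,
                                   signals_are_phases = TRUE)
    }
    summarize_pairs(K, do.call(rbind, pr_all), mean_order_r = mean(r_all))
  })
  out <- do.call(rbind, rows)
  out$delta_Kr <- c(NA, diff(out$control * out$mean_order_r))
  out <- out[, c("control", "mean_exponent", "sd_exponent",
                 "validity_fraction", "mean_order_r", "delta_Kr",
                 "n_pairs_analyzed", "n_valid")]
  class(out) <- c("phasecrit_sweep", class(out))
  out
}
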