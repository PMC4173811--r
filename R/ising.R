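# 2-D Ising model: simulation, sub-lattice series extraction, and the
# temperature sweep feeding the phase/DFA pipeline.

#' Critical temperature of the 2-D Ising model
#'
#' Onsager's exact value in `J = k = 1` units: `2 / log(1 + sqrt(2))`,
#' about 2.269, separating the magnetised and disordered phases.
#'
#' @return A single number.
#' @export
ising_critical_temperature <- function() 2 / log(1 + sqrt(2))

#' Number of sub-lattice pairs
#'
#' An `L x L` lattice divided into `block x block` sub-lattices yields
#' `(L/block)^2` block-mean time series and `choose((L/block)^2, 2)`
#' distinct pairs (96 and block 8: 144 series, 10,296 pairs).
#'
#' @param L Lattice edge length.
#' @param block Sub-lattice edge length; must divide `L`.
#' @return Number of distinct series pairs.
#' @export
ising_n_pairs <- function(L = 96L, block = 8L) {
  if (L %% block != 0) stop("block must divide L")
  choose((L / block)^2, 2)
}

#' Simulate the 2-D Ising model and extract sub-lattice series
#'
#' Metropolis Monte Carlo on an `L x L` lattice of spins in `{-1, +1}`
#' with the 4-nearest-neighbour Hamiltonian, `J = k = 1`, periodic
#' boundaries and checkerboard update order (two half-lattice passes per
#' sweep). After `burn_in` sweeps, one sample per sweep is recorded: the
#' mean spin of every `block x block` sub-lattice, giving
#' `(L/block)^2` time series in `[-1, 1]`.
#'
#' @param temperature Temperature `T` (in `J = k = 1` units; the critical
#'   value is [ising_critical_temperature()]).
#' @param L Lattice edge (default 96).
#' @param n_sweeps Recorded sweeps (default 64,000).
#' @param burn_in Equilibration sweeps discarded before recording
#'   (default 2,000).
#' @param block Sub-lattice edge (default 8; must divide `L`).
#' @param seed Optional integer seed.
#' @param init `"random"` (default) or `"aligned"` initial spins.
#' @param record_lattice Keep the final lattice configuration.
#' @return List with `series` (matrix, one row per sub-lattice, one
#'   column per sweep), `magnetization` (global mean spin per sweep),
#'   `acceptance` (data frame: energy change `dH`, proposals, acceptances,
#'   and the Metropolis probability `min(1, exp(-dH/T))`), `temperature`,
#'   and optionally `lattice`.
#' @examples
#' sim <- ising_simulate(1e5, L = 24, n_sweeps = 500, burn_in = 100, seed = 1)
#' dim(sim$series)  # 9 series x 500 sweeps
#' @export
ising_simulate <- function(temperature, L = 96L, n_sweeps = 64000L,
                           burn_in = 2000L, block = 8L, seed = NULL,
                           init = c("random", "aligned"),
                           record_lattice = FALSE) {
  init <- match.arg(init)
  if (L %% block != 0) stop("block must divide L")
  if (temperature <= 0) stop("temperature must be positive")
  res <- with_seed(seed,
    ising_sim_cpp(as.integer(L), temperature, as.integer(n_sweeps),
                  as.integer(burn_in), as.integer(block),
                  init == "aligned", record_lattice))
  dH <- c(-8, -4, 0, 4, 8)
  acc <- data.frame(dH = dH, proposed = res$proposed,
                    accepted = res$accepted,
                    prob_theory = pmin(1, exp(-dH / temperature)))
  out <- list(series = res$series, magnetization = res$magnetization,
              acceptance = acc, temperature = temperature,
              L = L, block = block)
  if (record_lattice) out$lattice <- res$lattice
  out
}

#' Temperature sweep of the Ising model through the phase pipeline
#'
#' For each temperature: simulate the lattice, extract the sub-lattice
#' block-mean series, and run the full pipeline (analytic phase, unwrap,
#' phase difference, rate of change, DFA, ML-DFA) on every pair - or a
#' seeded random subset of pairs - then aggregate.
#'
#' @param temperatures Vector of temperatures.
#' @param L,n_sweeps,burn_in,block,init As in [ising_simulate()].
#' @param pair_subset Number of pairs to analyse per temperature
#'   (default `Inf` = all pairs); a seeded subset is drawn when fewer.
#' @param seed Integer root seed.
#' @param min_window DFA minimum window (default 8, the simulated-data
#'   convention).
#' @param n_windows Number of DFA window sizes (default 20).
#' @param detail Return the per-pair table as an attribute.
#' @return Data frame of class `"phasecrit_sweep"`, one row per
#'   temperature: `control`, `mean_exponent`, `sd_exponent`,
#'   `validity_fraction`, `n_pairs_analyzed`, `n_valid`.
#' @examples
#' \donttest{
#' sw <- ising_sweep(c(2.5, 1e5), L = 24, n_sweeps = 2000, burn_in = 500,
#'                   pair_subset = 10, seed = 1)
#' sw
#' }
#' @export
ising_sweep <- function(temperatures, L = 96L, n_sweeps = 64000L,
                        burn_in = 2000L, block = 8L, pair_subset = Inf,
                        seed = 1L, min_window = 8L, n_windows = 20L,
                        init = "random", detail = FALSE) {
  stopifnot(length(temperatures) >= 1)
  all_detail <- list()
  rows <- lapply(seq_along(temperatures), function(ti) {
    Tt <- temperatures[ti]
    sim <- ising_simulate(Tt, L = L, n_sweeps = n_sweeps, burn_in = burn_in,
                          block = block, seed = child_seed(seed, ti),
                          init = init)
    pr <- pair_pipeline(sim$series, pair_subset = pair_subset,
                        seed = child_seed(seed, 1000L + ti),
                        min_window = min_window, n_windows = n_windows,
                        signals_are_phases = FALSE)
    if (detail) all_detail[[as.character(Tt)]] <<- pr
    summarize_pairs(Tt, pr)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("phasecrit_sweep", class(out))
  if (detail) attr(out, "detail") <- all_detail
  out
}
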