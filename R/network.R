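# Delayed weighted-network Kuramoto model: delay construction from
# distances, simulation, connectivity disruptions, and the coupling
# sweep over node pairs.

#' Delay matrix from a distance matrix
#'
#' Scales pairwise delays as `D_ij = mean_delay * L_ij / <L>` where `<L>`
#' is the mean over nonzero off-diagonal distances (zero entries encode
#' "no connection", not zero length). By construction the mean delay
#' over connected pairs equals `mean_delay` exactly. Delay units are
#' integration steps (`dt`-compatible): `step_counts` is the rounded
#' delay, and a delay rounding to 0 means instantaneous coupling.
#'
#' @param L Symmetric non-negative distance matrix (zero diagonal).
#' @param mean_delay Target mean delay `<D>` in integration steps
#'   (default 11); 0 yields instantaneous coupling throughout.
#' @return List of class `"delay_matrix"` with `values` (scaled delays)
#'   and `step_counts` (integer matrix).
#' @export
delays_from_distances <- function(L, mean_delay = 11) {
  L <- as.matrix(L)
  if (nrow(L) != ncol(L)) stop("distance matrix must be square")
  if (any(L < 0)) stop("distances must be non-negative")
  if (max(abs(L - t(L))) > 1e-8) stop("distance matrix must be symmetric")
  off <- L[row(L) != col(L)]
  nz <- off[off > 0]
  if (mean_delay != 0 && length(nz) == 0)
    stop("all distances are zero: cannot scale delays")
  D <- if (mean_delay == 0) L * 0 else mean_delay * L / mean(nz)
  structure(list(values = D, step_counts = matrix(as.integer(round(D)),
                                                  nrow(D), ncol(D))),
            class = "delay_matrix")
}

#' Simulate the delayed network Kuramoto model
#'
#' Euler-Maruyama integration of the network model
#' `dphi_i = (omega_i + (K/N) sum_j C_ij sin(phi_j(t - D_ij) - phi_i)) dt
#' + noise`, with per-edge delayed phase lookups from a ring buffer.
#' History before `t = 0` is backfilled by natural-frequency rotation
#' from the random initial phases. `N` in the `K/N` prefactor is the
#' total node count.
#'
#' @param C Weight matrix (zero diagonal, non-negative; typically
#'   row-normalised so connected rows sum to 1).
#' @param distances Symmetric distance matrix (used with `mean_delay`
#'   to build delays), or NULL with `delays` supplied.
#' @param coupling Coupling strength `K`.
#' @param mean_delay Mean delay in integration steps (default 11).
#' @param delays Optional precomputed `"delay_matrix"`.
#' @param mean_freq_hz Mean natural frequency in Hz (default 60, the
#'   gamma band).
#' @param freq_sd SD of natural frequencies (default 5).
#' @param noise_sd Noise SD in radians (default 1.25).
#' @param dt Integration step in seconds (default 1e-3).
#' @param n_steps Recorded steps (default 1e5).
#' @param seed Optional integer seed.
#' @param omega Optional natural-frequency vector (overrides the draw).
#' @return List with `phases` (`N x n_steps`, unwrapped), `omega`,
#'   `delays` and call parameters.
#' @export
network_simulate <- function(C, distances = NULL, coupling,
                             mean_delay = 11, delays = NULL,
                             mean_freq_hz = 60, freq_sd = 5,
                             noise_sd = 1.25, dt = 1e-3, n_steps = 1e5L,
                             seed = NULL, omega = NULL) {
  C <- as.matrix(C)
  N <- nrow(C)
  stopifnot(ncol(C) == N, all(C >= 0), all(diag(C) == 0), dt > 0,
            noise_sd >= 0)
  if (is.null(delays)) {
    delays <- if (is.null(distances) || mean_delay == 0)
      structure(list(values = C * 0,
                     step_counts = matrix(0L, N, N)), class = "delay_matrix")
    else delays_from_distances(distances, mean_delay)
  }
  stopifnot(inherits(delays, "delay_matrix"))
  if (max(delays$step_counts) >= n_steps)
    stop("configuration error: delay of ", max(delays$step_counts),
         " steps exceeds the simulated horizon")
  with_seed(seed, {
    if (is.null(omega)) omega <- rnorm(N, 2 * pi * mean_freq_hz, freq_sd)
    stopifnot(length(omega) == N)
    phi0 <- runif(N, -pi, pi)
    phases <- network_sim_cpp(C, delays$step_counts, omega, phi0,
                              coupling, noise_sd, dt, as.integer(n_steps))
    list(phases = phases, omega = omega, delays = delays,
         coupling = coupling, dt = dt, n_steps = n_steps)
  })
}

#' Remove all cross-hemisphere connections
#'
#' Zeroes every weight that extends from one hemisphere into the other;
#' within-hemisphere entries are untouched (no renormalisation).
#'
#' @param C Weight matrix.
#' @param hemisphere Vector of two distinct labels, one per node.
#' @return Modified weight matrix.
#' @export
disconnect_hemispheres <- function(C, hemisphere) {
  C <- as.matrix(C)
  stopifnot(length(hemisphere) == nrow(C))
  if (length(unique(hemisphere)) != 2)
    stop("exactly two hemisphere labels are required")
  cross <- outer(hemisphere, hemisphere, `!=`)
  C[cross] <- 0
  C
}

#' Degree- and weight-preserving randomization of connectivity
#'
#' Rewires the network at random while preserving each node's out-degree
#' and its multiset of outgoing weights exactly. A list of outgoing
#' weight stubs is made (one entry per nonzero weight, tagged with its
#' source node); two stubs are drawn at a time and their nodes are
#' connected to each other with the respective selected weights, unless
#' they share a node or are already connected, in which case new stubs
#' are drawn. A stub-matching dead end triggers a restart; after
#' `max_restarts` failed attempts an error is raised (never a silent
#' self-loop or duplicate edge).
#'
#' @param C Weight matrix (zero diagonal).
#' @param seed Integer seed.
#' @param max_restarts Maximum restarts before giving up (default 100).
#' @return Randomized weight matrix with the same per-node outgoing
#'   weight multisets.
#' @export
randomize_connectivity <- function(C, seed = 1L, max_restarts = 100L) {
  C <- as.matrix(C)
  N <- nrow(C)
  stopifnot(all(diag(C) == 0))
  nz <- which(C != 0, arr.ind = TRUE)
  stub_node <- nz[, 1]
  stub_w <- C[nz]
  n_stub <- length(stub_node)
  if (n_stub %% 2L != 0L)
    stop("odd number of outgoing weights: stub matching impossible")
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      out <- matrix(0, N, N)
      remaining <- sample.int(n_stub)           # shuffled stub order
      alive <- rep(TRUE, n_stub)
      n_left <- n_stub
      dead <- FALSE
      while (n_left > 0L) {
        placed <- FALSE
        for (try in 1:200) {
          pick <- if (n_left == 2L) which(alive)
                  else sample(which(alive), 2L)
          a <- stub_node[pick[1]]; b <- stub_node[pick[2]]
          if (a != b && out[a, b] == 0 && out[b, a] == 0) {
            out[a, b] <- stub_w[pick[1]]
            out[b, a] <- stub_w[pick[2]]
            alive[pick] <- FALSE
            n_left <- n_left - 2L
            placed <- TRUE
            break
          }
          if (n_left == 2L) break               # last two stubs incompatible
        }
        if (!placed) { dead <- TRUE; break }
      }
      if (!dead) return(out)
    }
    stop("randomization failed after ", max_restarts, " restarts")
  })
}

#' Per-cluster connectivity summary
#'
#' For each cluster label: the mean over member nodes of the summed
#' outgoing weights (row sums) and the mean out-degree (count of nonzero
#' outgoing entries). Apply it to a raw (pre-normalisation) weight
#' matrix to compare clusters by connection strength; on a row-normalised
#' matrix every connected row sums to 1 by construction.
#'
#' @param C Weight matrix.
#' @param clusters Vector of cluster labels covering all nodes.
#' @return Data frame: `cluster`, `n_nodes`, `mean_weight_per_node`,
#'   `mean_degree`.
#' @export
cluster_summary <- function(C, clusters) {
  C <- as.matrix(C)
  stopifnot(length(clusters) == nrow(C))
  w <- rowSums(C)
  deg <- rowSums(C != 0)
  out <- do.call(rbind, lapply(split(seq_len(nrow(C)), clusters), function(ix)
    data.frame(n_nodes = length(ix),
               mean_weight_per_node = mean(w[ix]),
               mean_degree = mean(deg[ix]))))
  data.frame(cluster = rownames(out), out, row.names = NULL)
}

#' Coupling sweep of the delayed network model
#'
#' For each coupling value: simulate the network, discard the initial
#' transient, compute the mean order parameter, and run DFA + ML-DFA on
#' the rate of change of phase difference for every node pair (or a
#' seeded subset). `delta_Kr` is the first difference of `K * mean_r`
#' along the grid.
#'
#' @param couplings Ascending vector of coupling values.
#' @param connectome List with at least `C` and `L` (e.g. from
#'   [synthetic_connectome()]), or supply `C` and `distances` directly.
#' @param C,distances Explicit matrices (used when `connectome` is NULL).
#' @param pair_subset Pairs analysed per coupling (default all).
#' @param seed Integer root seed.
#' @param cluster_labels Optional per-node labels; adds a per-cluster
#'   mean-exponent attribute (intra-cluster pairs only).
#' @param discard_frac Initial fraction of steps dropped (default 0.1).
#' @param min_window,n_windows DFA window scheme.
#' @param detail Keep per-pair tables as an attribute (the per-pair
#'   exponent matrix can be built from them).
#' @inheritParams network_simulate
#' @return Data frame of class `"phasecrit_sweep"` (one row per
#'   coupling), with attributes `detail` and `clusters` on request.
#' @export
network_sweep <- function(couplings, connectome = NULL, C = NULL,
                          distances = NULL, mean_delay = 11,
                          mean_freq_hz = 60, freq_sd = 5, noise_sd = 1.25,
                          dt = 1e-3, n_steps = 1e5L, pair_subset = Inf,
                          seed = 1L, cluster_labels = NULL,
                          discard_frac = 0.1, min_window = 8L,
                          n_windows = 20L, detail = FALSE) {
  stopifnot(!is.unsorted(couplings))
  if (!is.null(connectome)) {
    C <- connectome$C
    distances <- connectome$L
    if (is.null(cluster_labels)) cluster_labels <- connectome$clusters
  }
  stopifnot(!is.null(C))
  all_detail <- list()
  rows <- lapply(seq_along(couplings), function(ki) {
    K <- couplings[ki]
    sim <- network_simulate(C, distances, coupling = K,
                            mean_delay = mean_delay,
                            mean_freq_hz = mean_freq_hz, freq_sd = freq_sd,
                            noise_sd = noise_sd, dt = dt, n_steps = n_steps,
                            seed = child_seed(seed, ki))
    keep <- seq.int(floor(discard_frac * n_steps) + 1L, n_steps)
    ph <- sim$phases[, keep, drop = FALSE]
    r <- order_parameter(ph)$mean_r
    pr <- pair_pipeline(ph, pair_subset = pair_subset,
                        seed = child_seed(seed, 2000L + ki),
                        min_window = min_window, n_windows = n_windows,
                        signals_are_phases = TRUE)
    if (detail) all_detail[[as.character(K)]] <<- pr
    summarize_pairs(K, pr, mean_order_r = r)
  })
  out <- do.call(rbind, rows)
  out$delta_Kr <- c(NA, diff(out$control * out$mean_order_r))
  out <- out[, c("control", "mean_exponent", "sd_exponent",
                 "validity_fraction", "mean_order_r", "delta_Kr",
                 "n_pairs_analyzed", "n_valid")]
  class(out) <- c("phasecrit_sweep", class(out))
  if (detail) attr(out, "detail") <- all_detail
  if (!is.null(cluster_labels) && detail)
    attr(out, "clusters") <- cluster_labels
  out
}

#' Per-pair exponent matrix from a sweep detail table
#'
#' Symmetric matrix of valid DFA exponents for one coupling value; pairs
#' without a valid exponent are NA (written as empty cells in CSV).
#'
#' @param pr Per-pair table (from the `detail` attribute of
#'   [network_sweep()], one element).
#' @param n_nodes Number of nodes.
#' @return `n_nodes x n_nodes` numeric matrix with NA off the valid set.
#' @export
pair_exponent_matrix <- function(pr, n_nodes) {
  M <- matrix(NA_real_, n_nodes, n_nodes)
  v <- pr$valid & !is.na(pr$exponent)
  M[cbind(pr$i[v], pr$j[v])] <- pr$exponent[v]
  M[cbind(pr$j[v], pr$i[v])] <- pr$exponent[v]
  M
}
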