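---
title: "Detecting long-range temporal correlations in phase synchronization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting long-range temporal correlations in phase synchronization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasecrit)
```

## The problem and the method

Neural synchronization is weak and fluctuates from moment to moment.
Rather than averaging those fluctuations away (as coherence-type
measures do), `phasecrit` asks whether they are themselves structured:
whether the *rate of change of the phase difference* between two
oscillatory signals carries long-range temporal correlations (LRTCs), a
statistical signature associated with dynamical systems near a critical
regime.

The pipeline implemented by `analyze_pair()` is:

1. *(optional)* zero-phase bandpass filtering (`bandpass()`);
2. instantaneous phase per signal via the analytic signal
   $s_a(t) = s(t) + i\,H[s(t)]$, with $H$ the Hilbert transform
   (`analytic_phase()`);
3. unwrapping of each wrapped phase (`unwrap_phase()`);
4. the unwrapped phase difference $\phi_1(t) - \phi_2(t)$
   (`phase_difference()`);
5. its first difference, the rate of change (`rate_of_change()`) —
   taken because the phase difference itself is unbounded, while
   detrended fluctuation analysis assumes a bounded increment process;
6. detrended fluctuation analysis (`dfa()`): global mean removal,
   cumulative summation, per-window linear detrending, and the root
   mean square fluctuation $F(n)$ over log-spaced window sizes $n$;
7. ML-DFA (`mldfa()`): a model-selection test that accepts the DFA
   exponent $H$ (the slope of $\log_{10} F(n)$ vs $\log_{10} n$) only
   when a straight line is the best description of the fluctuation
   plot.

$H \approx 0.5$ indicates uncorrelated (white) fluctuations; $0.5 < H <
1$ indicates LRTCs; a fully synchronized pair has a constant phase
difference, no fluctuations, and therefore no valid exponent — the loss
of validity is itself informative, marking the onset of full
synchronization.

## ML-DFA: the validity test

A fluctuation plot always increases with window size, so a regression
slope with a high $r^2$ is easy to obtain even when the plot is not a
power law. ML-DFA guards against this. The log-fluctuations are scaled
to $[0, 100]$,

$$\mathrm{lF}_{scaled} = 100 \times
  \frac{\mathrm{lF} - \mathrm{lF}_{min}}{\mathrm{lF}_{max} - \mathrm{lF}_{min}},$$

and each candidate curve family $f$ is fitted by maximising the
pseudo-log-likelihood

$$\log L = \sum_i y_i \log p_i, \qquad
  p_i = \frac{|f(x_i)|}{\sum_j |f(x_j)|},$$

with $x$ the log window sizes and $y$ the scaled values. The scaled
values act as pseudo-counts; because $\log p_i$ is closest to zero
where the fluctuations (and hence $p_i$) are largest, the largest —
least well-estimated — windows carry the least weight. The candidate
set comprises polynomials of degree 1–5, root models
$a_1 (x + a_2)^{1/K} + a_3$ for $K = 2, 3, 4$, a logarithmic and an
exponential model, and continuous piecewise-linear splines with 2–4
segments (2 to 8 free parameters). Fits are compared with the
small-sample-corrected AIC,

$$\mathrm{AICc} = -2 \log L + 2k + \frac{2k(k+1)}{n-k-1},$$

appropriate because a plot has only $n \approx 20$ points. The
exponent is reported as valid only when the degree-1 polynomial attains
the *strict* minimum; an exact tie with any rival invalidates the plot
(a conservative tie-break that avoids false LRTC claims). A fit that
dips below zero at any design point is infeasible and excluded, as is a
model whose optimisation fails; if every model fails the verdict is
invalid with a diagnostic, never an error.

### Numerical choices

The pseudo-likelihood is non-quadratic, so each family is optimised by
multi-start Nelder–Mead (20 starts, iteration cap 5000, tolerance
1e-8), implemented in C++. Every start is an ordinary-least-squares
fit conditional on sampled values of the nonlinear parameters (shift of
the root/logarithm, rate of the exponential, spline breakpoints), so
the simplex only polishes a near-optimal profile; the multi-start phase
runs with a bounded iteration budget and the best start is then
re-polished at the full tolerance. Spline breakpoints are constrained
to the interior of the log-size range with a minimum separation of one
inter-point gap. Negative fitted values attract a soft penalty during
the search and a hard infeasibility mark at the optimum. All logarithms
of the fluctuation plot are base 10 (the slope is base-invariant).

Windows are the canonical non-overlapping scheme starting at the first
sample, with the trailing partial window discarded; 20 log-spaced sizes
between `min_window` and $N/10$. The minimum window is 8 samples for
simulated series with no characteristic time scale and about one second
of samples (`min_window_s = 1`) for oscillatory physiological data, so
that each window spans many cycles. "First detrended, then cumulatively
summed" is implemented as global mean removal before integration — the
standard DFA — with the linear detrending applied per window.

## Validation models

The package ships the generative models used to validate the framework
end to end. Each is first-class, seeded, and tested.

**FARIMA surrogates** (`farima_generate()`, `surrogate_pair()`).
FARIMA(0, $d$, 0) with $|d| < 1/2$ is fractionally integrated Gaussian
noise with autocovariances $\rho(k) = \rho(k-1)(k-1+d)/(k-d)$ (so
$\rho(1) = d/(1-d)$) and DFA exponent $d + 1/2$; AR(1)/MA(1) parts are
applied after fractional integration. Two exact samplers are provided:
Hosking's Durbin–Levinson recursion (the classical algorithm; $O(n^2)$)
and circulant embedding ($O(n \log n)$, exact in distribution, the
default so that $2^{18}$-sample experiments remain affordable on one
CPU); tests cross-check the two. The surrogate construction places half
the cumulative sum of $X$ in each of two cosine carriers with opposite
signs, $x_{1,2} = \cos(\omega t \pm \sum_s X(s)/2 f_s)$ with $\omega =
1$ rad/sample and $f_s = 600$, so the unwrapped phase difference is
$\sum X / f_s$ and its rate of change is $X/f_s$: the pipeline should
recover the exponent $d + 1/2$ that $X$ was built with. The exponent
grid endpoint $H = 1$ sits on the nonstationary boundary $d = 1/2$
where the autocovariances diverge; it is realised as $d = 0.4999$.
Additive Gaussian noise (`noise_sigma`) is applied to $x_1$ only,
before phase extraction, to probe robustness: intermediate noise bends
the fluctuation plot and ML-DFA rejects it; strong noise dominates the
phase relationship and valid exponents return near 0.5.

A note on fidelity: the per-sample correlation between the recovered
rate series and $X$ is about 0.87, not 1 — phase modulation components
above the carrier frequency cannot be represented in the analytic
phase and return as white estimation noise. That noise is invisible to
the $\ge 600$-sample DFA windows, which is why exponent recovery is
nonetheless essentially exact.

**Ising model** (`ising_simulate()`, `ising_sweep()`). A 96×96 (desk
scale: 48×48) lattice with the four-neighbour Hamiltonian, $J = k = 1$,
periodic boundaries, and critical temperature $T_c = 2/\ln(1+\sqrt2)
\approx 2.269$. Updates are random-site Metropolis, $L^2$ proposals per
sweep. A deterministic full-lattice order (checkerboard or typewriter)
was rejected deliberately: as $T \to \infty$ the acceptance probability
approaches 1 and such an order degenerates into a global spin negation
each sweep — a period-2 artifact that destroys the disordered limit the
validation depends on; random-site proposals keep that limit genuinely
random while sampling the same equilibrium distribution. Block-mean
time series over 8×8 sub-lattices (one sample per sweep after a
2,000-sweep burn-in, random initial spins) feed the full pipeline,
including the analytic-signal step.

**Noisy Kuramoto model** (`kuramoto_simulate()`, `kuramoto_sweep()`).
200 oscillators, natural frequencies $\mathcal N(2\pi \cdot 22\,
\mathrm{Hz}, \sigma_\omega = 15)$ (beta band), noise SD $\sigma_i =
0.32$ rad, $dt = 10^{-3}$ s, 6,100 steps. Euler–Maruyama integration
with per-step noise increments of variance $\sigma_i^2 \, dt$ (the
continuous process has covariance $\sigma_i^2/T$ with $T = 1$ s); the
mean-field identity $\tfrac{K}{N}\sum_j \sin(\phi_j - \phi_i) = K r
\sin(\psi - \phi_i)$ makes each step $O(N)$. The model yields phases
directly, so the pipeline skips the analytic-signal step. The
infinite-$N$ critical coupling for a zero-centred normal frequency
density is $K_c = 2/(\pi g(0)) = 2\sigma_\omega\sqrt{2/\pi}$
(`critical_coupling()`), about 23.94 for $\sigma_\omega = 15$. Sweeps
report the mean order parameter $\bar r$ and $\Delta(Kr)$, the first
difference of $K \bar r$ along the grid, whose peak marks maximal
synchronization flux. Each replicate (seed) draws one frequency
realization and holds it fixed across the whole coupling grid — one
system swept through $K$ — and the first 10% of steps are discarded as
transient before analysis.

**Delayed network model** (`network_simulate()`, `network_sweep()`).
66 noisy Kuramoto oscillators (gamma band: $2\pi\cdot 60$ Hz, SD 5,
noise 1.25 rad) on a weighted connectome with per-edge delays $D_{ij} =
\langle D\rangle L_{ij}/\langle L\rangle$, where $\langle L\rangle$ is
taken over nonzero off-diagonal distances (zero encodes "no
connection") and $\langle D\rangle = 11$ integration steps by default;
delays round to integer steps and a delay of 0 means instantaneous
coupling. History before $t = 0$ is backfilled by natural-frequency
rotation from the random initial phases. One convention deserves
emphasis: with a row-normalised weight matrix (connected rows sum
to 1) the weighted input $\sum_j C_{ij} \sin(\cdot)$ is already an
average over sources, so the drive is $K \sum_j C_{ij} \sin(\cdot)$
with no additional $1/N$ — an extra $1/N$ on top of row normalisation
would cap the drive at $K/66$ rad/s and no transition would occur
anywhere in the studied coupling range.

**Synthetic connectome** (`synthetic_connectome()`). A purely synthetic
stand-in for an empirical 66-region structural connectome: two mirrored
33-node hemispheres (homolog of node $i$ at $67-i$), six planted
clusters of sizes 11, 5, 8, 14, 5, 11 plus 12 unclustered nodes, the
central cluster (nodes 27–40) given the largest weights and strong
homologous cross-hemisphere links, distances from mirrored random 3-D
coordinates. The dynamics matrix `C` is row-normalised; the raw weights
`C_raw` are returned separately because "mean outgoing weight per node"
is identically 1 for every connected row after normalisation —
cluster-strength summaries (`cluster_summary()`) are meaningful on the
raw matrix. Connectivity disruptions are `disconnect_hemispheres()`
(zero every cross-hemisphere weight, touch nothing else) and
`randomize_connectivity()` (stub-matching rewiring that preserves every
node's out-degree and outgoing-weight multiset exactly, with restarts
on dead ends and an explicit error rather than a silent self-loop).

## What the generators do and do not emulate

The surrogates give ground-truth exponents; the Ising and Kuramoto
models probe the pipeline across order/disorder transitions; the
network model adds heterogeneous weights and delays. None of them
emulate real neurophysiological recordings: no 1/f background, no
artifacts, no nonstationary amplitude dynamics, no volume conduction.
A pass on these models shows the machinery is correct and calibrated on
known dynamics, not that any particular empirical signal contains
LRTCs. For physiological data the bandpass step and the 1-s minimum
window matter; the reference configuration is a beta-band analysis
(15.5–27.5 Hz at 512 Hz).

## Desk-scale study sizes

The shipped tests and the acceptance script run the full experiments at
reduced sizes chosen for a single CPU: FARIMA recovery uses 10
repetitions of $2^{18}$ samples per grid point (the original used 100
repetitions of $2^{22}$); the Ising sweep uses a 48×48 lattice with
16,000 recorded sweeps and all 630 block pairs; the Kuramoto sweep uses
seeded 300-pair subsets and 2 replicate systems per coupling; the
network experiment runs all 2,145 node pairs at $10^5$ steps for the
zero-coupling baseline and 200–300-pair subsets at $3\times10^4$ steps
for coupling scans. Tolerances in the tests are those of the original
quantities, not widened to match the reduced sizes.

## Known limitations

* The ML-DFA verdict is a heuristic model-selection test, not a
  hypothesis test; "valid" means the linear model was not beaten, with
  sharpness set by the $[0,100]$ pseudo-count scaling. Near regime
  boundaries (e.g. couplings just below full synchronization, where
  fluctuation plots carry a genuine noise-to-drift crossover) the
  verdict is sensitive to that calibration, and reported validity
  fractions there should be read qualitatively.
* At very high Ising temperatures the pipeline returns exponents
  slightly above 0.5 — block series retain short-range correlations
  from the update dynamics and the analytic phase of noise-like series
  adds structure of its own; the asymptote should not be interpreted as
  a property of the lattice alone.
* Hosking's recursion is $O(n^2)$ and impractical beyond about
  $2^{15}$ samples; the default circulant sampler is exact but requires
  a nonnegative-definite circulant embedding (guaranteed in practice
  for the implemented autocovariances; checked at run time).
* FARIMA orders are limited to $p, q \in \{0, 1\}$ with Gaussian
  innovations; multifractal DFA, higher-order detrending and confidence
  intervals on exponents are out of scope.
* The synthetic connectome reproduces the gross architecture of an
  empirical connectome (hemispheres, clusters, a heavy central
  cluster), not its fine structure; analyses that depend on the fine
  structure — in particular the relative ordering of clustered versus
  randomized connectivity in mean exponent — need the empirical
  matrices, which users can supply as CSV (`read_matrix_csv()`,
  `read_labels()`).

## A worked example

```{r example, eval = FALSE}
sp <- surrogate_pair(2^16, d = 0.25, seed = 1)    # target H = 0.75
res <- analyze_pair(sp$x1, sp$x2, fs = 600, min_window = 600, seed = 1)
res
plot(res)
summary(res$mldfa)
```

The verdict prints the validity flag, the exponent when valid, and a
provenance hash of the analysis configuration; `summary()` lists every
candidate model with its AICc.
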