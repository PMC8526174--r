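---
title: "Probing network structure with dynamics: co-activation and sequential activation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing network structure with dynamics: co-activation and sequential activation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A network's *structural connectivity* (SC) is its wiring diagram: here always a
binary, symmetric adjacency matrix $A$ of a simple undirected graph.
*Functional connectivity* (FC) is any node-by-node matrix summarizing
statistical relationships in activity simulated (or recorded) on that
substrate. How faithfully FC reflects SC — the SC/FC correlation — depends on
the dynamics, on the network architecture, and, centrally for this package, on
*which kind* of FC one measures:

* **co-activation (FCsim)** — simultaneous activity: same-time co-excitation
  counts for discrete dynamics, zero-lag correlations for continuous ones;
* **sequential activation (FCseq)** — time-lagged activity: one-step-offset
  co-excitation counts or lagged correlations.

The package's statistic, `scfc_correlation()`, is the Pearson correlation
between the flattened off-diagonal entries of $A$ and of an FC matrix, over
all ordered pairs $i \neq j$, excluding missing (zero-variance) FC entries
pairwise. Because Pearson correlation is invariant under positive affine
rescaling, raw counts and normalized FC give identical coefficients.

Four dynamics classes serve as probes:

1. **SER cellular automaton** (`ser_*`): each node is susceptible (S),
   excited (E) or refractory (R). Synchronous update against the time-$t$
   state: S$\to$E if at least one neighbour is excited, or spontaneously with
   probability $f$; E$\to$R deterministically; R$\to$S with probability $p$.
   Discreteness makes both FC classes parameter-free:
   $C_{ij}=\sum_t c_i(t)c_j(t)$ and $S_{ij}=\sum_t c_i(t)c_j(t-1)$ with
   $c_i(t)$ the excitation indicator.
2. **Kuramoto phase oscillators** (`kuramoto_*`):
   $\dot\theta_i=\omega_i+\frac{k}{N}\sum_j A_{ij}\sin(\theta_j-\theta_i)+\sigma u$,
   integrated by Euler–Maruyama. FC is built from the windowed *effective
   frequency* $\Omega_i(t)$, correlated at lag 0 (FCsim) and at a small
   positive lag (FCseq).
3. **Coupled logistic maps** (`logistic_*`):
   $x_i(t+1)=R_i x_i(t)(1-x_i(t))+\frac{k}{N}\sum_j A_{ij}(x_j(t)-x_i(t))$,
   hard-clipped to $[0,1]$ after each synchronous update; $R_i\in(3.7,3.9)$
   puts the uncoupled maps in the chaotic regime. FCsim/FCseq are the lag-0 and
   lag-1 correlations of the state series.
4. **FitzHugh–Nagumo units** (`fhn_*`): the two-variable excitable/oscillatory
   membrane model with diffusive coupling normalized by the mean degree, and
   spike-raster FC described below.

## Graph generators and topology destruction

* `make_modular(4, 15, 0.23)` — four 15-cliques whose edges are each rewired
  with probability 0.23 (one endpoint kept, the other redrawn uniformly from
  the kept endpoint's non-neighbours). Edge count is exactly conserved at 420
  (density 0.23 on 60 nodes). The redraw may land in any clique, including the
  original one; forcing a different clique is a stricter reading we did not
  adopt, since the uniform redraw already links cliques with high probability.
* `make_standard()` — Erdős–Rényi $G(n,p)$ (via igraph), Barabási–Albert
  growth, and the ring lattice with `ring_neighbors` nearest neighbours.
  BA growth is implemented in-package to pin the exact convention: an
  $m$-node edgeless seed, each incoming node attaching to $m$ *distinct*
  degree-proportional targets, giving exactly $(n-m)\,m$ edges (416 at
  $n=60$, $m=8$). A "15 nearest neighbours" ring is symmetrically infeasible;
  we use 7 per side ($k=14$, 420 edges), which also matches the convention
  that 10% randomization of the 60-node substrates is 50 edge changes
  ($50/420 \approx 0.12 \approx 0.11$).
* `make_hierarchical(3)` — deterministic hierarchical scale-free modular
  graph: start from a 4-clique; at each level create three replicas and
  attach each replica's corner nodes *and its hub* to the central hub. The
  textbook corner-only rule gives 159 edges at 64 nodes and attaching all
  replica nodes gives 192; the corners-plus-replica-hubs variant is the
  documented construction in this package because it reproduces the
  64-node / 174-edge benchmark graph exactly (levels 1..3: 6, 36, 174 edges).
* `randomize_degree_preserving()` — Markov-chain double-edge swaps; exactly
  `n_swaps` *successful* swaps, a proposal cap of `100 * n_swaps`, and a
  diagnostic error when no legal swap exists (e.g. a triangle or a star).
* `rewire_one_endpoint()` — destroy a random edge, reconnect one endpoint to
  a uniformly chosen non-neighbour (excluding the just-removed partner so
  every step changes the graph). Edge count conserved, degrees not; applied
  to the ring lattice this passes through a small-world regime.
* `graph_from_stoichiometry()` / `read_stoichiometry_sbml()` — the
  metabolite-projection graph: $A_{ij}=1$ iff $(SS^{\mathsf T})_{ij}\neq 0$,
  $i \neq j$.
* `graph_from_weights()` — threshold + symmetrize a weighted connectivity
  matrix (edge accepted if *either* direction passes, optionally after
  $\log_{10}$).

Graphs used as dynamics substrates must be connected (synchronization and
wave-propagation measures are uninterpretable otherwise); generators resample
disconnected draws with a deterministically derived seed and a warning, and
the sweep driver requests connected substrates. Node indexing is 1-based
throughout, the native R convention; 0-based edge lists are detected and
shifted on read.

## Numerical choices

**SER.** The initial state excites `round(0.06 n)` nodes (half-up, floor of
one) and assigns S or R equiprobably to the rest. Counts accumulate over the
full raster including the initial column (the formulas sum over all available
time steps); `include_initial = FALSE` trims it, and `normalize = TRUE`
divides by the run count — both provably irrelevant to the SC/FC coefficient.
Spontaneous excitation applies only to susceptible nodes; recovery passes
through S (the deterministic corner $f=1, p=1$ cycles E→R→S with period 3).

**Kuramoto.** Euler–Maruyama with $\sqrt{dt}$ noise scaling (a literal
$\sigma u\,dt$ mode is available via `noise_sqrt_dt = FALSE`). Phases
accumulate unwrapped — wrapping would corrupt the effective frequency. The
effective frequency is the centred moving average of one-step increments over
$\pm\Delta t$ ($\Delta t = 20$ steps), which telescopes to
$[\theta(t+\Delta t)-\theta(t-\Delta t)]/2\Delta t$; the series is trimmed to
its valid support. Natural frequencies are redrawn per run, uniform on
$(0, 1)$ by default; the intrinsic sweep widens this interval about its
midpoint. The sequential lag is 20 grid steps = 2 time units at $dt = 0.1$.
A lag far below the $2\Delta t = 40$-step averaging window would be
numerically indistinguishable from lag 0 (the moving average's
autocorrelation is triangular in the lag); 2 time units is the smallest
delay whose SC/FC curve separates from the co-activation group before
lagged correlations decay to zero, which we verified directly on an
Erdős–Rényi substrate (lags 0 and 1 time units cluster, lag 2 is distinct,
lags ≥ 3 decay).

**Logistic maps.** Clipping is hard truncation to $[0,1]$ applied after the
full synchronous update — the simplest contract consistent with keeping the
state in the unit interval, exercised by a dedicated arithmetic example.
$R_i$ is redrawn per run; the intrinsic sweep shifts the interval midpoint at
fixed width 0.2. No transient is discarded by default (a `transient` option
exists). Aggregation deliberately differs from SER/Kuramoto: the SC/FC
coefficient is computed per run and then averaged, with the spread across
runs as the error.

**FitzHugh–Nagumo.** Model constants $\gamma=1$, $\beta=0.6$,
$\tau_x=1\,$ms, $\tau_y=0.1\,$s; Euler step 0.1 ms; output sampled at 1 ms;
run length 180 s by default (tests and the acceptance battery use 20 s runs
to keep the suite at desk scale — the contrast of interest is already
resolved there). The fixed point solves
$x^3 + 3(1/\beta-\gamma)x + 3a/\beta = 0$ ($x^3+2x+4=0$ at $a=0.8$);
$a=0.8$ places it on the stable left branch (excitable), $a=0$ inside the
unstable region (oscillatory limit cycle). Initial conditions are uniform on
a small box around the fixed point ($x^*\pm 0.1$, $y^*\pm 0.05$): a quiet
start, so excitable activity is nucleated by noise and propagates along
edges rather than firing once in a synchronized transient.

Noise enters the membrane variable only, as Euler–Maruyama on the fast time
scale: per-step amplitude $\sigma\sqrt{dt/\tau_x}$ with $\sigma = 0.15$. A
literal $\sigma\,dt/\tau_x$ scaling is provided for sensitivity analysis but
leaves the excitable network silent — the per-step kick is two orders of
magnitude below the excitation barrier, no spontaneous spike occurs in
minutes of simulated time, and no FC can be defined.

The default coupling is $k = 0.14$, i.e. $k/\langle d\rangle = 0.01$ on the
60-node benchmark substrates. This is deliberately *sub-critical*: a single
spiking neighbour shifts a resting node's effective equilibrium by about
$(k/\langle d\rangle)\cdot 3.2/0.39$ (spike amplitude over the linearized
restoring rate), which balances the excitation barrier ($\approx 0.36$, rest
state to the middle nullcline branch) at $k/\langle d\rangle \approx 0.044$.
At or above that value propagation is deterministic: one nucleation recruits
the whole graph in a sub-millisecond avalanche, co-activation swamps both
regimes, and the excitable/oscillatory contrast disappears (we measured the
connected-pair crossing-delay excess collapsing onto zero lag). In the
sub-critical band propagation is noise-assisted with millisecond per-hop
delays, and the two regimes separate: oscillations express co-activation,
excitable dynamics express sequential activation.

Spike detection is upward threshold crossing ($x$ crosses 1 from below,
evaluated on the 1 ms samples), not level occupancy: an excursion stays above
threshold for tens of milliseconds (the recovery variable's time scale), so
occupancy would let one spike fill many 1 ms bins and the fine/coarse counts
would differ by bin-width bookkeeping rather than by dynamics. FCsim is the
co-activation count matrix of the 1 ms event raster; FCseq is the
co-activation count matrix of the 12 ms *disjoint*-window raster minus FCsim
— the coarse window captures simultaneous plus sequential events, so the
difference isolates the sequential component. Entries can be negative and are
not clamped; both matrices are symmetric, a conceptual difference from the
directed SER sequential matrix. No refractory suppression is applied in
detection: the trajectory itself enforces refractoriness.

## Sweeps, seeding and aggregation

`sweep_spec()` + `run_sweep()` drive the three experiment axes:
*randomization* (fractions of a full schedule — 500 swaps for the 60-node
substrates, 200 for the hierarchical graph, i.e. 50 and 20 changes per 10% —
or absolute swap counts; double-edge swaps by default, one-endpoint rewiring
for the ring lattice), *coupling* (Kuramoto/logistic only; the SER model has
no coupling parameter), and *intrinsic* (recovery probability $p$ for SER,
frequency-interval width for Kuramoto, $R$-interval midpoint for the maps).

Every random stage draws its seed from the master seed through a counter
scheme (`derive_seed()`, a polynomial hash modulo $2^{31}-1$), so results are
bit-reproducible, independent of evaluation order, and parallelizable by
construction; execution is serial. Infeasible grid points (a swap request on
a swapless graph) become missing rows with a diagnostic, and the sweep
continues.

Aggregation mirrors each model's convention: SER and Kuramoto accumulate FC
over runs, correlate once per graph seed, and report mean ± sd across graph
seeds; logistic maps and FHN correlate per run and report mean ± sd across
(pooled) runs. `sweep_report()` writes a tidy CSV (one row per grid point per
FC class) and optionally a two-curve figure with error bars;
`plot.scfc_sweep()` draws the same panel.

## What the synthetic substrates do and do not show

All experiments run on generated graphs whose ensembles are fully specified
(modular, ER, BA, ring lattice, deterministic hierarchical), so every
qualitative claim in the test suite is a statement about those ensembles at
the stated sizes — 60–64 nodes, densities near 0.23 — under the stated
dynamics parameters. Real structural networks differ in ways the generators
do not emulate: weighted and directed edges, degree–degree correlations,
geometric embedding, community sizes far from four equal cliques, and
measurement noise in the empirical FC pipeline. Passing the battery therefore
demonstrates that the *implementation* reproduces the architecture–dynamics
interactions on the benchmark ensembles, not that those interactions
generalize to any particular empirical network.

Problem sizes in the tests were chosen to resolve each directional claim with
one-sided comparisons of means at comfortable margins: SER ensembles of
1000 runs, oscillator and map ensembles of 20 runs, FHN at 3 × 20 s runs, five
graph seeds per condition. The full-scale conventions (10 000 SER runs,
100 oscillator runs, 50 map runs, 10 × 180 s FHN runs, ten graph seeds)
remain the package defaults.

## Known limitations

* Dynamics substrates are binary undirected graphs; no weighted or directed
  coupling, no multilayer structure.
* The FHN coupling/noise working point is a package choice within the
  sub-critical band (see above); exploring the criticality boundary
  systematically is left to the user via `fhn_params()`.
* FC estimators are correlation/count based; no transfer entropy, Granger
  causality or spectral coherence.
* The SER sequential matrix is used asymmetrically (all ordered pairs) in the
  SC/FC statistic; `symmetrize = TRUE` in `scfc_correlation()` provides the
  $S + S^{\mathsf T}$ sensitivity variant.
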