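# Networked FitzHugh-Nagumo units. The cubic nullcline intersected with the
# linear nullcline x - beta*y + a = 0 places the fixed point either where
# perturbations decay after a single spike (excitable regime, a = 0.8) or
# inside the unstable region producing sustained limit-cycle oscillations
# (oscillatory regime, a = 0). Spikes are detected by level-exceedance of the
# membrane variable; co-activation uses fine (1 ms) bins and sequential
# activation uses a coarse window with the fine co-activation subtracted.

#' Parameters of the networked FitzHugh-Nagumo model
#'
#' Defaults follow the excitable-regime benchmark configuration:
#' `gamma = 1`, `beta = 0.6`, `tau_x = 0.001` s, `tau_y = 0.1` s, noise
#' `sigma = 0.15` on the membrane variable only (Euler–Maruyama
#' discretization, per-step amplitude `sigma * sqrt(dt/tau_x)`), Euler step
#' 0.1 ms, output sampled at 1 ms. The coupling `k` is divided by the mean
#' degree of the substrate graph at simulation time; the default `k = 0.14`
#' gives a normalized coupling `k / <d> = 0.01` on the 60-node,
#' density-0.23 substrates (`<d> = 14`).
#'
#' The default coupling is deliberately sub-critical. For these model
#' constants a single spiking neighbour shifts a resting node's effective
#' equilibrium by roughly `(k/<d>) * 3.2 / 0.39` (spike amplitude over the
#' linearized restoring rate), while the excitation barrier — the distance
#' from the rest state to the middle branch of the cubic nullcline — is
#' about 0.36. The two balance at `k/<d> = 0.044`: at or above that value
#' propagation is deterministic and a single nucleation recruits the graph
#' in a sub-millisecond avalanche, so co-activation swamps both regimes and
#' the excitable/oscillatory distinction in the functional connectivity
#' disappears. In the sub-critical band around `k/<d> = 0.01` propagation
#' is noise-assisted with millisecond-scale per-hop delays: the excitable
#' regime then expresses sequential activation while the oscillatory regime
#' expresses co-activation, which is the contrast the model probes.
#'
#' @param gamma,beta,a model constants (dimensionless); `a` shifts the linear
#'   nullcline: 0.8 = excitable, 0 = oscillatory.
#' @param tau_x,tau_y time scales (seconds) of membrane and recovery variable.
#' @param k coupling strength (divided by the mean degree at run time).
#' @param sigma noise amplitude on the membrane variable.
#' @param noise_scaling `"sqrt_dt_over_tau"` (default; Euler–Maruyama on the
#'   `t/tau_x` time scale, per-step amplitude `sigma * sqrt(dt/tau_x)`),
#'   `"per_step"` (per-step amplitude `sigma`), or `"dt_over_tau"`
#'   (amplitude `sigma * dt/tau_x`; at the benchmark constants this leaves
#'   the excitable network silent), for sensitivity analyses.
#' @param dt Euler step (seconds).
#' @param t_total run length (seconds).
#' @param sample_interval output sampling bin (seconds); must be a multiple
#'   of `dt`.
#' @param spike_threshold binarization level on the membrane variable.
#' @param window_seq coarse window (seconds) for sequential activation; must
#'   be a multiple of `sample_interval`.
#' @param n_runs ensemble size.
#' @return an object of class `fhn_params`.
#' @export
fhn_params <- function(gamma = 1, beta = 0.6, a = 0.8, tau_x = 0.001,
                       tau_y = 0.1, k = 0.14, sigma = 0.15, dt = 1e-4,
                       t_total = 180, sample_interval = 1e-3,
                       spike_threshold = 1, window_seq = 0.012, n_runs = 10,
                       noise_scaling = c("sqrt_dt_over_tau", "per_step",
                                         "dt_over_tau")) {
  stopifnot(tau_x > 0, tau_y > 0, dt > 0, t_total > 0,
            sample_interval >= dt, window_seq >= sample_interval, n_runs >= 1)
  noise_scaling <- match.arg(noise_scaling)
  if (abs(sample_interval / dt - round(sample_interval / dt)) > 1e-8) {
    stop("sample_interval must be a multiple of dt", call. = FALSE)
  }
  if (abs(window_seq / sample_interval - round(window_seq / sample_interval)) > 1e-8) {
    stop("window_seq must be a multiple of sample_interval", call. = FALSE)
  }
  structure(list(gamma = gamma, beta = beta, a = a, tau_x = tau_x,
                 tau_y = tau_y, k = k, sigma = sigma, dt = dt,
                 t_total = t_total, sample_interval = sample_interval,
                 spike_threshold = spike_threshold, window_seq = window_seq,
                 n_runs = as.integer(n_runs), noise_scaling = noise_scaling),
            class = "fhn_params")
}

#' Fixed point of the uncoupled FitzHugh-Nagumo unit
#'
#' Intersection of the cubic nullcline `y = gamma x - x^3/3` with the linear
#' nullcline `y = (x + a)/beta`; x* solves
#' `x^3 + 3(1/beta - gamma) x + 3a/beta = 0` (for the default constants and
#' `a = 0.8` this is `x^3 + 2x + 4 = 0`).
#'
#' @param params `fhn_params` object.
#' @return list with components `x` and `y` (the real root closest to the
#'   real axis; the default parameters admit exactly one real root).
#' @export
fhn_fixed_point <- function(params = fhn_params()) {
  roots <- polyroot(c(3 * params$a / params$beta,
                      3 / params$beta - 3 * params$gamma, 0, 1))
  xr <- Re(roots[which.min(abs(Im(roots)))])
  list(x = xr, y = (xr + params$a) / params$beta)
}

#' Simulate networked FitzHugh-Nagumo dynamics
#'
#' Euler integration (compiled inner loop) with Gaussian noise on the
#' membrane variable, sampled down to `sample_interval`. Initial conditions,
#' when not supplied, are uniform on a small box around the fixed point
#' (`x* +- 0.1`, `y* +- 0.05`): a quiet start, so that in the excitable
#' regime every excitation is nucleated by noise and propagates along edges
#' (a wide initialization box instead fires the whole network in one
#' degenerate synchronized cascade at t = 0).
#'
#' @param A adjacency matrix.
#' @param params `fhn_params` object.
#' @param x0,y0 optional initial conditions.
#' @param seed optional RNG seed.
#' @return object of class `fhn_traces`: list with `x`, `y` (nodes x samples),
#'   `sample_interval` and `params`.
#' @export
fhn_simulate <- function(A, params = fhn_params(), x0 = NULL, y0 = NULL,
                         seed = NULL) {
  A <- as_adjacency(A, require_edge = TRUE)
  n <- nrow(A)
  mean_deg <- mean(rowSums(A))
  with_seed(seed, {
    if (is.null(x0) || is.null(y0)) {
      fp <- fhn_fixed_point(params)
      if (is.null(x0)) x0 <- fp$x + stats::runif(n, -0.1, 0.1)
      if (is.null(y0)) y0 <- fp$y + stats::runif(n, -0.05, 0.05)
    }
    n_steps <- round(params$t_total / params$dt)
    sample_every <- round(params$sample_interval / params$dt)
    noise_step <- params$sigma * switch(params$noise_scaling,
      per_step = 1,
      sqrt_dt_over_tau = sqrt(params$dt / params$tau_x),
      dt_over_tau = params$dt / params$tau_x)
    out <- fhn_integrate_cpp(A, as.numeric(x0), as.numeric(y0),
                             params$gamma, params$beta, params$a,
                             params$tau_x, params$tau_y,
                             params$k / mean_deg, noise_step, params$dt,
                             as.integer(n_steps), as.integer(sample_every))
    structure(list(x = out$x, y = out$y,
                   sample_interval = params$sample_interval, params = params),
              class = "fhn_traces")
  })
}

#' Binarize membrane traces into a spike raster
#'
#' Spike detection by upward threshold crossing: a spike event occurs at
#' sample t when `x(t) > threshold` and `x(t-1) <= threshold` (a series that
#' starts above threshold counts a spike at its first sample). The raster
#' entry for node i and bin b is 1 iff at least one spike event falls inside
#' the (disjoint) bin. Detecting crossings rather than level occupancy makes
#' each spike contribute exactly one fine bin regardless of its width, so
#' fine- and coarse-window co-activation counts are on a common per-event
#' scale and their difference isolates sequential activity.
#'
#' @param x numeric matrix, nodes x samples, at `sample_interval` resolution.
#' @param threshold crossing threshold on the membrane variable.
#' @param bin bin width in seconds (>= `sample_interval`, a multiple of it).
#' @param sample_interval sampling resolution of `x` in seconds.
#' @return binary raster, nodes x floor(samples / samples_per_bin).
#' @export
binarize_spikes <- function(x, threshold = 1, bin = 1e-3,
                            sample_interval = 1e-3) {
  spb <- round(bin / sample_interval)
  if (spb < 1 || abs(bin / sample_interval - spb) > 1e-8) {
    stop("bin must be a positive multiple of sample_interval", call. = FALSE)
  }
  n <- nrow(x)
  above <- x > threshold
  cross <- above & !cbind(rep(FALSE, n), above[, -ncol(x), drop = FALSE])
  n_bins <- ncol(x) %/% spb
  if (n_bins < 1) stop("series shorter than one bin", call. = FALSE)
  hit <- cross[, seq_len(n_bins * spb), drop = FALSE]
  if (spb == 1L) return(matrix(as.integer(hit), n, n_bins))
  dim(hit) <- c(n, spb, n_bins)
  raster <- apply(hit, c(1, 3), any) * 1L
  matrix(as.integer(raster), n, n_bins)
}

#' Co-activation and sequential-activation FC from FHN traces
#'
#' `FCsim` is the co-activation count matrix of the fine
#' (`sample_interval`-wide, by default 1 ms) spike raster. `FCseq` is the
#' co-activation count matrix of the coarse (`window_seq`, by default 12 ms,
#' disjoint windows) raster minus `FCsim`: the coarse window captures both
#' simultaneous and sequential spikes, so subtracting the fine co-activity
#' isolates the sequential component. Entries may be negative and are not
#' clamped. Both matrices are symmetric (a conceptual difference from the
#' directed SER sequential matrix).
#'
#' @param traces `fhn_traces` object (or plain nodes x samples matrix of the
#'   membrane variable).
#' @param params `fhn_params` object; defaults to the params stored in
#'   `traces`.
#' @return an [fc_pair] with `model = "fhn"`.
#' @export
fhn_fc_pair <- function(traces, params = NULL) {
  if (inherits(traces, "fhn_traces")) {
    if (is.null(params)) params <- traces$params
    x <- traces$x
  } else {
    if (is.null(params)) stop("params required for a bare matrix", call. = FALSE)
    x <- traces
  }
  if (ncol(x) * params$sample_interval < 2 * params$window_seq) {
    stop("traces too short for two coarse windows", call. = FALSE)
  }
  fine <- binarize_spikes(x, params$spike_threshold,
                          params$sample_interval, params$sample_interval)
  coarse <- binarize_spikes(x, params$spike_threshold,
                            params$window_seq, params$sample_interval)
  fc_sim <- coactivation_matrix(fine)
  fc_seq <- coactivation_matrix(coarse) - fc_sim
  fc_pair(fc_sim, fc_seq, model = "fhn", n_runs = 1L)
}

#' FitzHugh-Nagumo randomization experiment
#'
#' SC/FC correlations of both classes while a modular substrate is
#' progressively randomized by degree-preserving swaps. For each level of the
#' swap schedule and each graph seed, `params$n_runs` independent runs are
#' simulated; the SC/FC correlation is computed per run on the off-diagonal
#' flattened matrices, and the mean and standard deviation across all runs are
#' reported.
#'
#' @param graph_seeds integer vector of graph seeds.
#' @param params `fhn_params` object.
#' @param swaps_schedule integer vector of swap counts (one sweep level each).
#' @param graph_spec list passed to [make_modular()] (fields `n_cliques`,
#'   `clique_size`, `rewire_p`), or a function `(seed) -> adjacency`.
#' @param seed master seed for the dynamics.
#' @return a `scfc_sweep` data frame (see [run_sweep()]).
#' @export
fhn_randomization_experiment <- function(graph_seeds, params = fhn_params(),
                                         swaps_schedule = seq(0, 500, by = 50),
                                         graph_spec = list(n_cliques = 4,
                                                           clique_size = 15,
                                                           rewire_p = 0.23),
                                         seed = 1) {
  spec <- sweep_spec(dynamics = "fhn",
                     graph = c(list(model = "modular"), graph_spec),
                     axis = "randomization",
                     grid = swaps_schedule, grid_unit = "swaps",
                     n_graph_seeds = length(graph_seeds),
                     params = params, master_seed = seed)
  run_sweep(spec)
}
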