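# Stochastic susceptible-excited-refractory (SER) cellular automaton on a
# graph. States are coded as integers: 0 = S, 1 = E, 2 = R. Because time and
# states are discrete, co-activation and sequential activation are defined in
# a parameter-free way from the binarized activity c_i(t) = 1 iff node i is
# excited at step t.

SER_S <- 0L
SER_E <- 1L
SER_R <- 2L

#' Parameters of the SER cellular automaton
#'
#' @param f spontaneous excitation probability per susceptible node per step.
#' @param p recovery probability per refractory node per step.
#' @param t_max number of synchronous update steps per run.
#' @param n_runs ensemble size (independent runs summed into the FC matrices).
#' @param frac_excited_init initial fraction of excited nodes (rounded
#'   half-up, floor of one node); the remaining nodes are S or R with equal
#'   probability.
#' @param include_initial include the initial condition (t = 0 column) in the
#'   co-activation and sequential-activation sums.
#' @param normalize divide ensemble FC counts by the number of runs (the
#'   SC/FC correlation is invariant to this, it only changes the scale).
#' @return an object of class `ser_params`.
#' @export
ser_params <- function(f = 0.001, p = 0.1, t_max = 10, n_runs = 10000,
                       frac_excited_init = 0.06, include_initial = TRUE,
                       normalize = FALSE) {
  stopifnot(f >= 0, f <= 1, p >= 0, p <= 1, t_max >= 1, n_runs >= 1,
            frac_excited_init > 0, frac_excited_init < 1)
  structure(list(f = f, p = p, t_max = as.integer(t_max),
                 n_runs = as.integer(n_runs),
                 frac_excited_init = frac_excited_init,
                 include_initial = isTRUE(include_initial),
                 normalize = isTRUE(normalize)),
            class = "ser_params")
}

#' Random initial SER state
#'
#' `round(frac_excited * n)` nodes (half-up, at least one) are excited; each
#' remaining node is independently susceptible or refractory with probability
#' one half.
#'
#' @param n node count (> 0).
#' @param frac_excited initial excited fraction in (0, 1).
#' @param seed optional RNG seed.
#' @return integer state vector (0 = S, 1 = E, 2 = R).
#' @export
ser_init <- function(n, frac_excited = 0.06, seed = NULL) {
  if (n < 1) stop("need at least one node", call. = FALSE)
  stopifnot(frac_excited > 0, frac_excited < 1)
  with_seed(seed, {
    n_exc <- max(1L, as.integer(floor(frac_excited * n + 0.5)))
    x <- ifelse(stats::runif(n) < 0.5, SER_S, SER_R)
    x[sample.int(n, n_exc)] <- SER_E
    as.integer(x)
  })
}

#' One synchronous SER update
#'
#' All rules are evaluated against the state at time t: an excited node
#' becomes refractory; a refractory node becomes susceptible with probability
#' `p`; a susceptible node becomes excited if at least one neighbour is
#' excited at time t, or spontaneously with probability `f`.
#'
#' @param x integer state vector (0 = S, 1 = E, 2 = R).
#' @param A adjacency matrix.
#' @param params `ser_params` object (only `f` and `p` are used).
#' @return the state vector at time t + 1.
#' @export
ser_step <- function(x, A, params) {
  if (length(x) != nrow(A)) stop("state length does not match graph", call. = FALSE)
  exc <- x == SER_E
  driven <- as.vector(A %*% exc) > 0
  new <- x
  new[exc] <- SER_R
  r <- which(x == SER_R)
  if (length(r)) new[r] <- ifelse(stats::runif(length(r)) < params$p, SER_S, SER_R)
  s <- which(x == SER_S)
  if (length(s)) {
    fire <- driven[s] | (stats::runif(length(s)) < params$f)
    new[s] <- ifelse(fire, SER_E, SER_S)
  }
  as.integer(new)
}

#' Simulate one SER run
#'
#' @param A adjacency matrix.
#' @param params `ser_params` object.
#' @param x0 optional initial state; drawn by [ser_init()] when `NULL`.
#' @param seed optional RNG seed.
#' @return binary activity raster, nodes x (t_max + 1); column t is the
#'   indicator of excitation at step t - 1 (column 1 is the initial state).
#' @export
ser_run <- function(A, params = ser_params(), x0 = NULL, seed = NULL) {
  A <- as_adjacency(A, require_edge = TRUE)
  n <- nrow(A)
  with_seed(seed, {
    x <- if (is.null(x0)) ser_init(n, params$frac_excited_init) else as.integer(x0)
    raster <- matrix(0L, n, params$t_max + 1L)
    raster[, 1L] <- (x == SER_E) * 1L
    for (t in seq_len(params$t_max)) {
      x <- ser_step(x, A, params)
      raster[, t + 1L] <- (x == SER_E) * 1L
    }
    raster
  })
}

#' Co-activation count matrix
#'
#' \eqn{C_{ij} = \sum_t c_i(t) c_j(t)}: the number of time steps at which
#' nodes i and j are excited simultaneously. Symmetric; the diagonal holds
#' each node's total excitation count and is excluded from downstream
#' statistics.
#'
#' @param raster binary activity raster (nodes x time).
#' @return numeric count matrix.
#' @export
coactivation_matrix <- function(raster) {
  if (length(raster) == 0) stop("empty raster", call. = FALSE)
  raster %*% t(raster)
}

#' Sequential-activation count matrix
#'
#' \eqn{S_{ij} = \sum_t c_i(t) c_j(t-1)}: the number of events in which node j
#' is excited one step before node i. Asymmetric in general.
#'
#' @param raster binary activity raster with at least two time columns.
#' @return numeric count matrix.
#' @export
sequential_matrix <- function(raster) {
  T_ <- ncol(raster)
  if (is.null(T_) || T_ < 2) stop("raster needs at least two time columns", call. = FALSE)
  raster[, -1L, drop = FALSE] %*% t(raster[, -T_, drop = FALSE])
}

#' SER ensemble functional connectivity
#'
#' Runs `params$n_runs` independent SER simulations (each re-initialized by
#' [ser_init()]) and accumulates the co-activation and sequential-activation
#' counts first over time within each run, then over the runs.
#'
#' @param A adjacency matrix.
#' @param params `ser_params` object.
#' @param seed optional RNG seed.
#' @return an [fc_pair] with components `sim` (co-activation) and `seq`
#'   (sequential activation).
#' @export
ser_ensemble_fc <- function(A, params = ser_params(), seed = NULL) {
  A <- as_adjacency(A, require_edge = TRUE)
  n <- nrow(A)
  with_seed(seed, {
    Csum <- matrix(0, n, n)
    Ssum <- matrix(0, n, n)
    for (r in seq_len(params$n_runs)) {
      raster <- ser_run(A, params)
      if (!params$include_initial) {
        Csum <- Csum + coactivation_matrix(raster[, -1L, drop = FALSE])
        Ssum <- Ssum + sequential_matrix(raster[, -1L, drop = FALSE])
      } else {
        Csum <- Csum + coactivation_matrix(raster)
        Ssum <- Ssum + sequential_matrix(raster)
      }
    }
    if (params$normalize) {
      Csum <- Csum / params$n_runs
      Ssum <- Ssum / params$n_runs
    }
    fc_pair(Csum, Ssum, model = "ser", n_runs = params$n_runs,
            normalized = params$normalize)
  })
}
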