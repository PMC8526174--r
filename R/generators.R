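# Graph generators.
#
# All generators return validated binary symmetric adjacency matrices of
# simple undirected graphs. Where a `connected = TRUE` flag is supported,
# disconnected draws are resampled with a deterministically derived seed (the
# synchronization and wave-propagation probes are uninterpretable on
# disconnected substrates); hitting the retry cap is an error, not a silent
# fallback.

retry_connected <- function(build, seed, connected, max_attempts = 100L) {
  A <- build(seed)
  if (!connected) return(A)
  attempt <- 0L
  while (!is_connected_adj(A)) {
    attempt <- attempt + 1L
    if (attempt > max_attempts) {
      stop("failed to draw a connected graph in ", max_attempts, " attempts",
           call. = FALSE)
    }
    seed2 <- if (is.null(seed)) NULL else derive_seed(seed, attempt)
    warning("disconnected draw resampled (attempt ", attempt, ")", call. = FALSE)
    A <- build(seed2)
  }
  A
}

#' Modular graph: rewired union of cliques
#'
#' Builds `n_cliques` disjoint cliques of `clique_size` nodes each, then visits
#' every edge once and, with probability `rewire_p`, keeps one uniformly chosen
#' endpoint and moves the other endpoint to a uniformly chosen non-neighbour of
#' the kept endpoint. Edge count is conserved exactly; the graph stays simple.
#' The defaults give the 60-node, 420-edge modular benchmark substrate of
#' density 0.23.
#'
#' @param n_cliques number of cliques (>= 2).
#' @param clique_size nodes per clique (>= 2).
#' @param rewire_p per-edge rewiring probability in `[0, 1]`.
#' @param seed optional RNG seed.
#' @param connected resample until connected (default `FALSE`; note
#'   `rewire_p = 0` is always disconnected).
#' @return adjacency matrix with `n_cliques * clique_size` nodes.
#' @export
#' @examples
#' A <- make_modular(4, 15, 0.23, seed = 1)
#' n_edges(A) # always 420
make_modular <- function(n_cliques = 4, clique_size = 15, rewire_p = 0.23,
                         seed = NULL, connected = FALSE) {
  if (n_cliques < 2 || clique_size < 2) {
    stop("need n_cliques >= 2 and clique_size >= 2", call. = FALSE)
  }
  if (!is.finite(rewire_p) || rewire_p < 0 || rewire_p > 1) {
    stop("rewire_p must be a probability in [0, 1]", call. = FALSE)
  }
  n <- n_cliques * clique_size
  build <- function(s) with_seed(s, {
    A <- matrix(0L, n, n)
    for (b in seq_len(n_cliques)) {
      idx <- (b - 1L) * clique_size + seq_len(clique_size)
      A[idx, idx] <- 1L
    }
    diag(A) <- 0L
    el <- edge_list(A)
    for (e in seq_len(nrow(el))) {
      if (stats::runif(1) >= rewire_p) next
      u <- el[e, 1]; v <- el[e, 2]
      if (A[u, v] == 0L) next # endpoint moved here by an earlier rewire
      keep <- if (stats::runif(1) < 0.5) u else v
      A[u, v] <- A[v, u] <- 0L
      cand <- which(A[keep, ] == 0L)
      cand <- cand[cand != keep]
      if (length(cand) == 0L) { # kept endpoint saturated; undo
        A[u, v] <- A[v, u] <- 1L
        next
      }
      w <- sample_one(cand)
      A[keep, w] <- A[w, keep] <- 1L
    }
    A
  })
  as_adjacency(retry_connected(build, seed, connected))
}

#' Standard random-graph ensembles
#'
#' Erdős–Rényi G(n, p), Barabási–Albert preferential attachment (growth from
#' an `m`-node edgeless seed; each new node attaches to `m` distinct existing
#' nodes with probability proportional to degree, so the graph has exactly
#' `(n - m) * m` edges), or a ring lattice in which every node is linked to its
#' `ring_neighbors` nearest neighbours (`ring_neighbors / 2` on each side; must
#' be even). The ring lattice is the starting point of the small-world rewiring
#' experiment, see [rewire_one_endpoint()].
#'
#' @param model `"erdos_renyi"`, `"barabasi_albert"` or `"watts_strogatz"`.
#' @param n node count.
#' @param param model parameter: edge probability `p` (ER), attachment count
#'   `m` (BA), or `ring_neighbors` (WS lattice).
#' @param seed optional RNG seed.
#' @param connected resample until connected (ER/BA; the ring lattice is
#'   deterministic and connected for `param >= 2`).
#' @return adjacency matrix.
#' @export
#' @examples
#' n_edges(make_standard("watts_strogatz", 60, 14)) # 420
#' n_edges(make_standard("barabasi_albert", 60, 8, seed = 1)) # 416
make_standard <- function(model = c("erdos_renyi", "barabasi_albert", "watts_strogatz"),
                          n, param, seed = NULL, connected = FALSE) {
  model <- match.arg(model)
  if (n < 2) stop("need n >= 2", call. = FALSE)
  build <- switch(model,
    erdos_renyi = {
      if (param < 0 || param > 1) stop("edge probability must be in [0, 1]", call. = FALSE)
      function(s) with_seed(s, igraph_to_adj(igraph::sample_gnp(n, param)))
    },
    barabasi_albert = {
      m <- as.integer(param)
      if (m < 1 || n <= m) stop("need 1 <= m < n for preferential attachment", call. = FALSE)
      function(s) with_seed(s, ba_growth(n, m))
    },
    watts_strogatz = {
      k <- as.integer(param)
      if (k < 2 || k %% 2 != 0 || k >= n) {
        stop("ring_neighbors must be even, >= 2 and < n", call. = FALSE)
      }
      function(s) ring_lattice(n, k)
    }
  )
  as_adjacency(retry_connected(build, seed, connected))
}

# Barabasi-Albert growth from an m-node edgeless seed; each incoming node
# attaches to m distinct targets sampled preferentially by degree (first
# incoming node attaches to the m seed nodes). Edge count: (n - m) * m.
ba_growth <- function(n, m) {
  A <- matrix(0L, n, n)
  repeated <- integer(0)
  targets <- seq_len(m)
  for (v in seq.int(m + 1L, n)) {
    A[v, targets] <- 1L
    A[targets, v] <- 1L
    repeated <- c(repeated, targets, rep.int(v, m))
    if (v == n) break
    targets <- integer(0)
    while (length(targets) < m) {
      x <- sample_one(repeated)
      if (!(x %in% targets)) targets <- c(targets, x)
    }
  }
  A
}

ring_lattice <- function(n, k) {
  i <- matrix(seq_len(n), n, n)
  d <- abs(i - t(i))
  d <- pmin(d, n - d)
  A <- (d >= 1 & d <= k / 2) * 1L
  storage.mode(A) <- "integer"
  A
}

#' Deterministic hierarchical scale-free modular graph
#'
#' Recursive construction starting from a 4-clique: at every level the current
#' module is replicated three times and the corner (peripheral) nodes of each
#' replica, together with the replica's own hub, are linked to the central hub
#' of the original module. At `levels = 3` this yields 64 nodes and 174 edges,
#' a scale-free graph with embedded modular structure. (The textbook
#' corner-only attachment yields 159 edges at 64 nodes; attaching the replica
#' hubs as well is the variant adopted here — see the package vignette.)
#'
#' @param levels recursion depth (>= 1); `levels = 1` is the 4-clique.
#' @return adjacency matrix with `4^levels` nodes.
#' @export
#' @examples
#' A <- make_hierarchical(3)
#' nrow(A)    # 64
#' n_edges(A) # 174
make_hierarchical <- function(levels = 3) {
  if (!is.finite(levels) || levels < 1) stop("levels must be >= 1", call. = FALSE)
  h <- hier_build(as.integer(levels))
  as_adjacency(h$A)
}

hier_build <- function(levels) {
  if (levels == 1L) {
    A <- matrix(1L, 4, 4)
    diag(A) <- 0L
    return(list(A = A, hub = 1L, periph = 2:4))
  }
  g <- hier_build(levels - 1L)
  np <- nrow(g$A)
  n <- 4L * np
  A <- matrix(0L, n, n)
  for (b in 0:3) {
    idx <- b * np + seq_len(np)
    A[idx, idx] <- g$A
  }
  hub <- g$hub # hub of copy 1 stays the central hub
  periph <- integer(0)
  for (b in 1:3) {
    off <- b * np
    attach <- c(off + g$periph, off + g$hub)
    A[hub, attach] <- 1L
    A[attach, hub] <- 1L
    periph <- c(periph, off + g$periph)
  }
  list(A = A, hub = hub, periph = periph)
}

#' Metabolite-projection graph from a stoichiometric matrix
#'
#' Two metabolites are linked when they participate in at least one common
#' reaction: the adjacency matrix is the indicator of non-zero off-diagonal
#' entries of \eqn{S S^T}.
#'
#' @param S numeric stoichiometric matrix, metabolites x reactions.
#' @param tol magnitude below which an `S S^T` entry counts as zero.
#' @return adjacency matrix over the metabolites.
#' @export
graph_from_stoichiometry <- function(S, tol = 1e-9) {
  if (!is.matrix(S) || !is.numeric(S) || length(S) == 0) {
    stop("S must be a non-empty numeric matrix", call. = FALSE)
  }
  B <- S %*% t(S)
  A <- (abs(B) > tol) * 1L
  diag(A) <- 0L
  as_adjacency(A)
}

#' Binary graph from a weighted connectivity matrix
#'
#' Thresholds a (possibly asymmetric) square weight matrix into a simple
#' undirected graph: an edge is accepted if the weight in *either* direction
#' passes the threshold, optionally after a decimal-log transform
#' (non-positive weights never pass when transforming).
#'
#' @param W square numeric weight matrix.
#' @param threshold acceptance threshold (applied to `log10(W)` when
#'   `log10_transform` is `TRUE`, to `W` otherwise).
#' @param log10_transform compare `log10(W)` against `threshold`.
#' @return adjacency matrix.
#' @export
graph_from_weights <- function(W, threshold, log10_transform = TRUE) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("W must be a square matrix", call. = FALSE)
  }
  V <- if (log10_transform) suppressWarnings(log10(W)) else W
  pass <- is.finite(V) & V > threshold
  A <- (pass | t(pass)) * 1L
  diag(A) <- 0L
  as_adjacency(A)
}

#' Read a stoichiometric matrix from an SBML file
#'
#' Minimal SBML (Level 2/3 core) reader covering `listOfSpecies` and
#' `listOfReactions`/`speciesReference`: reactants enter with negative and
#' products with positive stoichiometry. Gzip-compressed files are supported.
#' Species flagged as boundary conditions are excluded.
#'
#' @param path SBML file (`.xml` or `.xml.gz`).
#' @return numeric matrix metabolites x reactions with species ids as row
#'   names and reaction ids as column names.
#' @export
read_stoichiometry_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0) stop("no species found in SBML file", call. = FALSE)
  ids <- xml2::xml_attr(sp_nodes, "id")
  boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition")
  ids <- ids[is.na(boundary) | boundary != "true"]
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  if (length(rx_nodes) == 0) stop("no reactions found in SBML file", call. = FALSE)
  S <- matrix(0, length(ids), length(rx_nodes),
              dimnames = list(ids, xml2::xml_attr(rx_nodes, "id")))
  for (j in seq_along(rx_nodes)) {
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(rx_nodes[[j]], paste0("./", side, "/speciesReference"))
      if (length(refs) == 0) next
      sp <- xml2::xml_attr(refs, "species")
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      if (side == "listOfReactants") st <- -st
      keep <- sp %in% ids
      S[sp[keep], j] <- S[sp[keep], j] + st[keep]
    }
  }
  S
}
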