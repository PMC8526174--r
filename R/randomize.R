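# Topology destruction: degree-preserving double-edge swaps and one-endpoint
# rewiring. Both conserve the edge count and simplicity; only the swap
# conserves the degree sequence.

#' Degree-preserving randomization by double-edge swaps
#'
#' Markov-chain randomization: repeatedly pick two random edges (a,b), (c,d)
#' sharing no node and replace them with (a,d), (c,b) (orientation chosen
#' uniformly), rejecting any proposal that would create a self-loop or a
#' multi-edge. Exactly `n_swaps` *successful* swaps are performed; rejected
#' proposals do not count. The degree of every node is preserved.
#'
#' @param A adjacency matrix with at least two edges.
#' @param n_swaps number of successful swaps to perform (>= 0).
#' @param seed optional RNG seed.
#' @param max_tries proposal cap; exceeding it (e.g. on a triangle, where no
#'   legal swap exists) raises a diagnostic error. Default `100 * n_swaps`.
#' @return randomized adjacency matrix; the input is not modified.
#' @export
#' @examples
#' A <- make_modular(seed = 1)
#' B <- randomize_degree_preserving(A, 500, seed = 2)
#' identical(degrees(A), degrees(B)) # TRUE
randomize_degree_preserving <- function(A, n_swaps, seed = NULL,
                                        max_tries = max(100 * n_swaps, 100)) {
  A <- as_adjacency(A)
  if (n_swaps < 0) stop("n_swaps must be >= 0", call. = FALSE)
  if (n_swaps == 0) return(A)
  el <- edge_list(A)
  m <- nrow(el)
  if (m < 2) stop("cannot swap: graph has fewer than 2 edges", call. = FALSE)
  with_seed(seed, {
    done <- 0L
    tries <- 0L
    while (done < n_swaps) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("no legal double-edge swap found: ", done, " of ", n_swaps,
             " swaps succeeded after ", max_tries, " proposals", call. = FALSE)
      }
      e <- sample.int(m, 2L)
      a <- el[e[1], 1]; b <- el[e[1], 2]
      c <- el[e[2], 1]; d <- el[e[2], 2]
      if (stats::runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      # propose (a,d) and (c,b)
      if (a == d || c == b) next          # self-loop
      if (length(unique(c(a, b, c, d))) < 4L) next # shared node
      if (A[a, d] == 1L || A[c, b] == 1L) next     # multi-edge
      A[a, b] <- A[b, a] <- 0L
      A[c, d] <- A[d, c] <- 0L
      A[a, d] <- A[d, a] <- 1L
      A[c, b] <- A[b, c] <- 1L
      el[e[1], ] <- sort(c(a, d))
      el[e[2], ] <- sort(c(c, b))
      done <- done + 1L
    }
    A
  })
}

#' One-endpoint rewiring
#'
#' Small-world style rewiring: at each step a random edge is destroyed and a
#' new edge is created between one of its two endpoints (chosen uniformly) and
#' a uniformly chosen node that is neither the kept endpoint, its current
#' neighbour, nor the just-removed partner. Edge count and simplicity are
#' conserved; the degree sequence generally is not. Applied to a ring lattice
#' this drives the graph through a small-world regime towards an
#' Erdős–Rényi-like topology.
#'
#' @param A adjacency matrix; must not be complete.
#' @param n_rewires number of rewiring steps (>= 0).
#' @param seed optional RNG seed.
#' @param max_tries proposal cap (default `100 * n_rewires`).
#' @return rewired adjacency matrix; the input is not modified.
#' @export
rewire_one_endpoint <- function(A, n_rewires, seed = NULL,
                                max_tries = max(100 * n_rewires, 100)) {
  A <- as_adjacency(A, require_edge = TRUE)
  if (n_rewires < 0) stop("n_rewires must be >= 0", call. = FALSE)
  n <- nrow(A)
  if (sum(A) == n * (n - 1)) {
    stop("cannot rewire a complete graph: no legal new edge exists", call. = FALSE)
  }
  if (n_rewires == 0) return(A)
  with_seed(seed, {
    el <- edge_list(A)
    m <- nrow(el)
    done <- 0L
    tries <- 0L
    while (done < n_rewires) {
      tries <- tries + 1L
      if (tries > max_tries) {
        stop("no legal rewiring found: ", done, " of ", n_rewires,
             " rewires succeeded after ", max_tries, " proposals", call. = FALSE)
      }
      e <- sample.int(m, 1L)
      ends <- el[e, ]
      keep <- sample_one(ends)
      other <- ends[ends != keep]
      cand <- which(A[keep, ] == 0L)
      cand <- cand[cand != keep & cand != other]
      if (length(cand) == 0L) next
      w <- sample_one(cand)
      A[keep, other] <- A[other, keep] <- 0L
      A[keep, w] <- A[w, keep] <- 1L
      el[e, ] <- sort(c(keep, w))
      done <- done + 1L
    }
    A
  })
}
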