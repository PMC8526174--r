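# Graph generators, randomization operators and builders.

test_that("modular generator conserves node and edge counts under rewiring", {
  A <- make_modular(4, 15, 0.23, seed = 1)
  expect_identical(nrow(A), 60L)
  expect_identical(n_edges(A), 420L) # 4 * choose(15, 2); rewiring moves, never deletes
  expect_true(isSymmetric(unclass(A)))
  expect_true(all(diag(A) == 0))

  A0 <- make_modular(4, 15, 0, seed = 2)
  expect_identical(n_edges(A0), 420L)
  # p = 0: exactly four disjoint 15-cliques
  g <- igraph::graph_from_adjacency_matrix(A0, "undirected")
  comps <- igraph::components(g)
  expect_equal(comps$no, 4)
  expect_true(all(comps$csize == 15))
  expect_true(all(igraph::transitivity(g, type = "localundirected") == 1))

  # p = 1 on a small instance: every edge visited; graph stays simple,
  # edge count conserved, across many seeds
  for (s in 1:25) {
    B <- make_modular(2, 3, 1, seed = s)
    expect_identical(nrow(B), 6L)
    expect_identical(n_edges(B), 6L)
    expect_true(all(B %in% c(0L, 1L)) && all(diag(B) == 0))
    expect_true(isSymmetric(unclass(B)))
  }
})

test_that("modular generator rejects invalid parameters", {
  expect_error(make_modular(1, 15, 0.2), "n_cliques")
  expect_error(make_modular(4, 15, 1.5), "probability")
})

test_that("standard ensembles match their expected edge statistics", {
  # ER: mean edge count ~ p * C(n,2) = 407.1 over many seeds
  m <- vapply(1:100, function(s) n_edges(make_standard("erdos_renyi", 60, 0.23, seed = s)),
              integer(1))
  expect_equal(mean(m), 0.23 * choose(60, 2), tolerance = 0.02)

  # BA growth from an 8-node edgeless seed: exactly (60 - 8) * 8 edges
  B <- make_standard("barabasi_albert", 60, 8, seed = 1)
  expect_identical(n_edges(B), 416L)
  expect_true(all(degrees(B) >= 8) || sum(degrees(B) < 8) <= 8) # only seed nodes can be below m

  # ring lattice: n * k / 2 edges, every degree k
  W <- make_standard("watts_strogatz", 60, 14)
  expect_identical(n_edges(W), 420L)
  expect_true(all(degrees(W) == 14L))

  expect_error(make_standard("barabasi_albert", 8, 8, seed = 1), "m < n")
  expect_error(make_standard("watts_strogatz", 60, 15), "even")
})

test_that("hierarchical construction hits its printed node and edge counts", {
  A <- make_hierarchical(3)
  expect_identical(nrow(A), 64L)
  expect_identical(n_edges(A), 174L)
  expect_true(igraph::is_connected(
    igraph::graph_from_adjacency_matrix(A, "undirected")))
  # base case: a single 4-clique
  A1 <- make_hierarchical(1)
  expect_identical(nrow(A1), 4L)
  expect_identical(n_edges(A1), 6L)
  expect_true(all(A1[upper.tri(A1)] == 1L))
})

test_that("degree-preserving randomization conserves the degree sequence", {
  A <- make_modular(seed = 3)
  expect_identical(randomize_degree_preserving(A, 0, seed = 1), A)
  B <- randomize_degree_preserving(A, 500, seed = 4)
  expect_identical(degrees(B), degrees(A))
  expect_identical(n_edges(B), n_edges(A))
  expect_false(identical(A, B))
  expect_true(all(diag(B) == 0) && all(B %in% c(0L, 1L)))
  # input untouched
  expect_identical(n_edges(A), 420L)
})

test_that("triangle admits no legal double-edge swap and errors diagnostically", {
  K3 <- matrix(1L, 3, 3); diag(K3) <- 0L
  expect_error(randomize_degree_preserving(K3, 1, seed = 1, max_tries = 500),
               "no legal double-edge swap")
})

test_that("one-endpoint rewiring conserves edge count and drives small-world transition", {
  W <- make_standard("watts_strogatz", 60, 14)
  expect_identical(rewire_one_endpoint(W, 0, seed = 1), W)
  R1 <- rewire_one_endpoint(W, 420, seed = 2)
  expect_identical(n_edges(R1), 420L)
  expect_true(all(diag(R1) == 0) && all(R1 %in% c(0L, 1L)))

  # 10% of edges rewired: clustering drops, mean shortest path sharply reduced
  g0 <- igraph::graph_from_adjacency_matrix(W, "undirected")
  cl0 <- igraph::transitivity(g0)
  pl0 <- igraph::mean_distance(g0)
  cl <- pl <- numeric(20)
  for (s in 1:20) {
    Rw <- rewire_one_endpoint(W, 42, seed = s)
    g <- igraph::graph_from_adjacency_matrix(Rw, "undirected")
    cl[s] <- igraph::transitivity(g)
    pl[s] <- igraph::mean_distance(g)
  }
  expect_lt(mean(cl), cl0)
  expect_lt(mean(pl), 0.8 * pl0) # path length collapses well before clustering
})

test_that("rewiring a complete graph is rejected", {
  K5 <- matrix(1L, 5, 5); diag(K5) <- 0L
  expect_error(rewire_one_endpoint(K5, 1, seed = 1), "complete")
})

test_that("stoichiometric projection equals the shared-reaction oracle", {
  # single reaction A -> B: one edge
  S1 <- matrix(c(-1, 1), 2, 1)
  A1 <- graph_from_stoichiometry(S1)
  expect_identical(n_edges(A1), 1L)

  # two reactions over disjoint metabolite sets: no cross edges
  S2 <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  A2 <- graph_from_stoichiometry(S2)
  expect_identical(A2[1:2, 3:4], matrix(0L, 2, 2))

  # random sparse +-1 matrix vs naive double loop over metabolite pairs
  set.seed(7)
  S <- matrix(sample(c(-1, 0, 0, 1), 60, replace = TRUE), 10, 6)
  A <- graph_from_stoichiometry(S)
  expected <- matrix(0L, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    if (i != j && sum(S[i, ] * S[j, ]) != 0) expected[i, j] <- 1L
  }
  expect_identical(unclass(A), expected)
})

test_that("weight thresholding symmetrizes by either-direction acceptance", {
  W0 <- matrix(0, 4, 4)
  expect_identical(n_edges(graph_from_weights(W0, -3)), 0L)

  W1 <- matrix(1, 4, 4); diag(W1) <- 0
  expect_identical(n_edges(graph_from_weights(W1, -3)), 6L) # log10(1)=0 > -3

  # exactly one passing direction per pair
  W <- matrix(0, 4, 4)
  W[1, 2] <- 1; W[3, 1] <- 0.5; W[4, 3] <- 2; W[2, 4] <- 1e-5
  A <- graph_from_weights(W, -3)
  expected <- matrix(0L, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j && (W[i, j] > 1e-3 || W[j, i] > 1e-3)) expected[i, j] <- 1L
  }
  expect_identical(unclass(A), expected)
})

test_that("graph files round-trip through edge list, CSV and GraphML", {
  A <- make_modular(2, 5, 0.3, seed = 9)
  for (ext in c("tsv", "csv", "graphml")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_graph_file(A, f)
    expect_identical(read_graph_file(f), A)
    unlink(f)
  }
  # 0-based edge lists are shifted on read
  f <- tempfile(fileext = ".tsv")
  write_graph_file(A, f, zero_based = TRUE)
  expect_identical(read_graph_file(f), A)
  unlink(f)
})

test_that("SBML stoichiometry reader recovers a hand-built model", {
  sbml <- system.file("extdata", "synthetic_toy_model.xml", package = "netscfc")
  S <- read_stoichiometry_sbml(sbml)
  expect_identical(dim(S), c(4L, 3L))
  # R1: A + B -> C, R2: C -> 2 D, R3: D -> A (ids in the fixture)
  expect_identical(unname(S[, "R1"]), c(-1, -1, 1, 0))
  expect_identical(unname(S[, "R2"]), c(0, 0, -1, 2))
  expect_identical(unname(S[, "R3"]), c(1, 0, 0, -1))
  A <- graph_from_stoichiometry(S)
  # shared-reaction pairs: A-B, A-C, B-C (R1), C-D (R2), D-A (R3)
  expect_identical(n_edges(A), 5L)
})

test_that("adjacency validation catches malformed matrices", {
  expect_error(as_adjacency(matrix(1:6, 2, 3)), "square")
  M <- matrix(0, 3, 3); M[1, 2] <- 1
  expect_error(as_adjacency(M), "symmetric")
  M2 <- diag(3)
  expect_error(as_adjacency(M2), "diagonal")
  M3 <- matrix(0, 3, 3)
  expect_error(as_adjacency(M3, require_edge = TRUE), "edge")
})
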