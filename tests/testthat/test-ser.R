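# SER cellular automaton: initialization, update rules, the deterministic
# ring wave, and the count-matrix constructions against brute-force oracles.

test_that("initial states have the prescribed excited count and S/R balance", {
  x <- ser_init(60, 0.06, seed = 1)
  expect_identical(sum(x == 1L), 4L) # round-half-up of 3.6
  x2 <- ser_init(100, 0.06, seed = 2)
  expect_identical(sum(x2 == 1L), 6L)
  expect_true(all(x %in% 0:2))

  # floor of one excited node even for tiny fractions
  expect_identical(sum(ser_init(10, 0.001, seed = 3) == 1L), 1L)

  # S and R equiprobable among the non-excited nodes
  set.seed(4)
  counts <- replicate(1000, {
    x <- ser_init(60, 0.06)
    c(sum(x == 0L), sum(x == 2L))
  })
  expect_equal(mean(counts[1, ]), 28, tolerance = 0.02)
  expect_equal(mean(counts[2, ]), 28, tolerance = 0.02)
  expect_error(ser_init(0, 0.06), "node")
})

test_that("update rules follow the three-state automaton", {
  A <- ring_adj(5)
  p <- ser_params(f = 0, p = 1, t_max = 1, n_runs = 1)
  # E -> R deterministically
  x <- c(1L, 0L, 0L, 0L, 0L)
  x1 <- ser_step(x, A, p)
  expect_identical(x1[1], 2L)
  # S with an excited neighbour fires even at f = 0
  expect_identical(x1[2], 1L)
  expect_identical(x1[5], 1L)
  # S without excited neighbour stays S at f = 0
  expect_identical(x1[3], 0L)
  # R -> S with p = 1; R stays R forever with p = 0
  xr <- rep(2L, 5)
  expect_identical(ser_step(xr, A, p), rep(0L, 5))
  p0 <- ser_params(f = 0, p = 0, t_max = 1, n_runs = 1)
  expect_identical(ser_step(xr, A, p0), rep(2L, 5))
  expect_error(ser_step(c(0L, 1L), A, p), "match")
})

test_that("deterministic ring wave matches the hand trace", {
  A <- ring_adj(5)
  p <- ser_params(f = 0, p = 1, t_max = 5, n_runs = 1)
  raster <- ser_run(A, p, x0 = c(1L, 0L, 0L, 0L, 0L))
  # t0: seed; t1: both neighbours of the seed; t2: the two far nodes; then out
  expect_identical(raster[, 1], c(1L, 0L, 0L, 0L, 0L))
  expect_identical(raster[, 2], c(0L, 1L, 0L, 0L, 1L))
  expect_identical(raster[, 3], c(0L, 0L, 1L, 1L, 0L))
  expect_identical(sum(raster[, 4:6]), 0L)
  # every node excited exactly once
  expect_identical(unname(rowSums(raster)), rep(1, 5))

  # co-activation: only the two t1 nodes and the two t2 nodes co-fire
  C <- coactivation_matrix(raster)
  off <- which(C > 0 & row(C) != col(C), arr.ind = TRUE)
  expect_identical(nrow(off), 4L) # two unordered pairs, both orientations
  expect_identical(C[2, 5], 1)
  expect_identical(C[3, 4], 1)

  # sequential matrix equals the brute-force oracle and captures the wave order
  Sm <- sequential_matrix(raster)
  expect_equal(Sm, oracle_sequential(raster))
  expect_identical(Sm[2, 1], 1) # node 2 fires one step after node 1
  expect_identical(Sm[1, 2], 0)
})

test_that("degenerate parameter corners behave as derived", {
  A <- ring_adj(6)
  # all-S start, f = 0: no excitation source, raster identically zero
  p <- ser_params(f = 0, p = 0.5, t_max = 8, n_runs = 1)
  expect_identical(sum(ser_run(A, p, x0 = rep(0L, 6), seed = 1)), 0L)
  # f = 1, p = 1, all-S start: lockstep period-3 cycle E -> R -> S -> E ...
  # (recovery passes through S; a refractory node is never excited directly)
  p2 <- ser_params(f = 1, p = 1, t_max = 6, n_runs = 1)
  raster <- ser_run(A, p2, x0 = rep(0L, 6), seed = 1)
  expect_identical(unname(raster[, 2:7]),
                   matrix(rep(c(1L, 0L, 0L), 2), 6, 6, byrow = TRUE))
})

test_that("count matrices match brute-force oracles on random rasters", {
  set.seed(11)
  for (rep in 1:5) {
    raster <- matrix(rbinom(8 * 12, 1, 0.3), 8, 12)
    expect_equal(coactivation_matrix(raster), oracle_coactivation(raster),
                 tolerance = 1e-12)
    expect_equal(sequential_matrix(raster), oracle_sequential(raster),
                 tolerance = 1e-12)
  }
  # explicit two-series example: c1 = (1,0,1), c2 = (1,1,0)
  r <- rbind(c(1, 0, 1), c(1, 1, 0))
  expect_identical(coactivation_matrix(r)[1, 2], 1)
  expect_identical(sequential_matrix(r)[1, 2], 1)  # c1(2)c2(1)
  expect_identical(sequential_matrix(r)[2, 1], 1)  # c2(1)c1(0)
  expect_error(sequential_matrix(matrix(1, 2, 1)), "two time columns")
})

test_that("every excited node is refractory one step later", {
  A <- make_modular(seed = 5, connected = TRUE)
  p <- ser_params(t_max = 10, n_runs = 1)
  set.seed(6)
  x <- ser_init(nrow(A), 0.06)
  for (t in 1:10) {
    xn <- ser_step(x, A, p)
    expect_true(all(xn[x == 1L] == 2L))
    x <- xn
  }
})

test_that("ensemble accumulation is linear over runs and bounded", {
  A <- ring_adj(5)
  p1 <- ser_params(f = 0.2, p = 0.5, t_max = 6, n_runs = 1)
  fc1 <- ser_ensemble_fc(A, p1, seed = 42)
  # one run reduces to the single-run matrices
  raster <- ser_run(A, p1, seed = 42)
  expect_equal(fc1$sim, coactivation_matrix(raster))
  expect_equal(fc1$seq, sequential_matrix(raster))

  # ensemble over all five single-seed deterministic initial conditions
  pd <- ser_params(f = 0, p = 1, t_max = 5, n_runs = 1)
  Cs <- matrix(0, 5, 5); Ss <- matrix(0, 5, 5)
  for (seed_node in 1:5) {
    x0 <- rep(0L, 5); x0[seed_node] <- 1L
    r <- ser_run(A, pd, x0 = x0)
    Cs <- Cs + coactivation_matrix(r)
    Ss <- Ss + sequential_matrix(r)
  }
  # the five waves tile the ring symmetrically: row sums all equal
  expect_true(all(rowSums(Cs) == rowSums(Cs)[1]))
  expect_true(all(Ss >= 0))

  # count bounds
  p3 <- ser_params(f = 0.05, p = 0.3, t_max = 5, n_runs = 20)
  fc <- ser_ensemble_fc(A, p3, seed = 7)
  expect_true(all(fc$sim >= 0) && all(fc$sim <= 6 * 20))
  expect_true(all(fc$seq >= 0) && all(fc$seq <= 5 * 20))
  expect_true(isSymmetric(fc$sim))
})

test_that("normalization and initial-column options only rescale or trim", {
  A <- ring_adj(6)
  pn <- ser_params(f = 0.1, p = 0.5, t_max = 6, n_runs = 10, normalize = TRUE)
  pr <- ser_params(f = 0.1, p = 0.5, t_max = 6, n_runs = 10)
  fcn <- ser_ensemble_fc(A, pn, seed = 3)
  fcr <- ser_ensemble_fc(A, pr, seed = 3)
  expect_equal(fcn$sim * 10, fcr$sim)
  # SC/FC correlation is invariant under the rescaling
  expect_equal(scfc_correlation(A, fcn$sim)$r, scfc_correlation(A, fcr$sim)$r,
               tolerance = 1e-12)
  # excluding the initial column can only reduce counts
  px <- ser_params(f = 0.1, p = 0.5, t_max = 6, n_runs = 10,
                   include_initial = FALSE)
  fcx <- ser_ensemble_fc(A, px, seed = 3)
  expect_true(all(fcx$sim <= fcr$sim))
})
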