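# Independent brute-force oracles for the FC constructions and the SC/FC
# statistic. These deliberately use naive double/triple loops so they share
# no code path with the package implementations.

oracle_coactivation <- function(raster) {
  n <- nrow(raster); T_ <- ncol(raster)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (t in seq_len(T_)) {
    C[i, j] <- C[i, j] + raster[i, t] * raster[j, t]
  }
  C
}

oracle_sequential <- function(raster) {
  n <- nrow(raster); T_ <- ncol(raster)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (t in 2:T_) {
    S[i, j] <- S[i, j] + raster[i, t] * raster[j, t - 1]
  }
  S
}

oracle_effective_frequency <- function(theta, window) {
  n <- nrow(theta); T_ <- ncol(theta)
  ts <- seq.int(window + 1L, T_ - window)
  Om <- matrix(0, n, length(ts))
  for (i in seq_len(n)) for (a in seq_along(ts)) {
    t <- ts[a]
    acc <- 0
    for (tp in seq.int(t - window, t + window - 1L)) {
      acc <- acc + theta[i, tp + 1L] - theta[i, tp]
    }
    Om[i, a] <- acc / (2 * window)
  }
  Om
}

oracle_lagged_cor <- function(series, lag) {
  n <- nrow(series); L <- ncol(series)
  FC <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- series[i, seq_len(L - lag)]
    xj <- series[j, seq.int(1 + lag, L)]
    if (stats::sd(xi) > 0 && stats::sd(xj) > 0) FC[i, j] <- stats::cor(xi, xj)
  }
  diag(FC) <- 0
  FC
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_scfc <- function(A, F) {
  off <- row(A) != col(A)
  a <- A[off]; f <- F[off]
  keep <- is.finite(f)
  oracle_pearson(a[keep], f[keep])
}

# small deterministic ring adjacency
ring_adj <- function(n) {
  i <- matrix(seq_len(n), n, n)
  d <- abs(i - t(i)); d <- pmin(d, n - d)
  A <- (d == 1) * 1L
  storage.mode(A) <- "integer"
  A
}

path3_adj <- function() {
  A <- matrix(0L, 3, 3)
  A[1, 2] <- A[2, 1] <- 1L
  A[2, 3] <- A[3, 2] <- 1L
  A
}
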