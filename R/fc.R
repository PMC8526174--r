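# Functional-connectivity containers and the lagged-correlation estimator
# shared by the oscillator and chaotic-map modules.

#' Pair of functional-connectivity matrices
#'
#' Container for the two FC classes extracted from one dynamics ensemble:
#' `sim` (co-activation: same-time co-excitation counts or zero-lag
#' correlations) and `seq` (sequential activation: one-step-offset counts or
#' lagged correlations).
#'
#' @param sim,seq square numeric matrices of equal dimension.
#' @param model character tag of the generating dynamics.
#' @param n_runs ensemble size the matrices were accumulated over.
#' @param normalized whether counts were divided by `n_runs`.
#' @param n_missing number of FC entries that were missing (zero variance) in
#'   every run (`NA` entries), per class.
#' @return an object of class `fc_pair`.
#' @export
fc_pair <- function(sim, seq, model = "unknown", n_runs = 1L,
                    normalized = FALSE, n_missing = c(sim = 0L, seq = 0L)) {
  stopifnot(is.matrix(sim), is.matrix(seq), all(dim(sim) == dim(seq)),
            nrow(sim) == ncol(sim))
  structure(list(sim = sim, seq = seq, model = model,
                 n_runs = as.integer(n_runs), normalized = isTRUE(normalized),
                 n_missing = n_missing),
            class = "fc_pair")
}

#' @export
print.fc_pair <- function(x, ...) {
  n <- nrow(x$sim)
  cat("Functional connectivity pair (", x$model, " dynamics)\n", sep = "")
  cat("  nodes:", n, " runs:", x$n_runs,
      if (x$normalized) " (normalized)" else " (raw counts/sums)", "\n")
  off <- row(x$sim) != col(x$sim)
  cat(sprintf("  FCsim  range: [%.4g, %.4g]  missing: %d\n",
              min(x$sim[off], na.rm = TRUE), max(x$sim[off], na.rm = TRUE),
              sum(is.na(x$sim[off]))))
  cat(sprintf("  FCseq  range: [%.4g, %.4g]  missing: %d\n",
              min(x$seq[off], na.rm = TRUE), max(x$seq[off], na.rm = TRUE),
              sum(is.na(x$seq[off]))))
  invisible(x)
}

#' Lagged Pearson-correlation functional connectivity
#'
#' Entry (i, j) is the Pearson correlation over time between series i at time
#' t and series j at time t + `lag`, computed over the overlapping support.
#' At `lag = 0` the matrix is symmetric (strict co-activation); positive lags
#' give the sequential-activation estimate. The diagonal is set to zero by
#' convention; pairs involving a zero-variance series are recorded as `NA`.
#'
#' @param series numeric matrix, nodes x time (e.g. effective frequencies,
#'   logistic-map states).
#' @param lag non-negative lag in series steps.
#' @return square matrix with zero diagonal, possibly containing `NA`.
#' @export
lagged_correlation_fc <- function(series, lag = 0) {
  lag <- as.integer(lag)
  if (lag < 0) stop("lag must be >= 0", call. = FALSE)
  L <- ncol(series)
  if (is.null(L) || L <= lag + 2) {
    stop("series too short for lag ", lag, call. = FALSE)
  }
  X <- t(series[, seq_len(L - lag), drop = FALSE])         # time x nodes, at t
  Y <- t(series[, seq.int(1 + lag, L), drop = FALSE])      # time x nodes, at t + lag
  sx <- apply(X, 2, stats::sd)
  sy <- apply(Y, 2, stats::sd)
  FC <- suppressWarnings(stats::cor(X, Y))
  FC[sx == 0, ] <- NA_real_
  FC[, sy == 0] <- NA_real_
  diag(FC) <- 0
  off <- row(FC) != col(FC)
  if (all(is.na(FC[off]))) {
    warning("all functional-connectivity entries are undefined (constant series)",
            call. = FALSE)
  }
  FC
}

# Accumulate possibly-NA per-run FC matrices: sum over the runs in which an
# entry is defined; entries defined in no run stay NA.
fc_accumulate <- function(mats) {
  n <- nrow(mats[[1]])
  total <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  for (M in mats) {
    ok <- !is.na(M)
    total[ok] <- total[ok] + M[ok]
    count <- count + ok
  }
  total[count == 0L] <- NA_real_
  list(sum = total, n_defined = count)
}
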