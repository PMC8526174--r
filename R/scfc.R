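# The structure-function correlation statistic: Pearson correlation between
# the flattened off-diagonal entries of the adjacency matrix and a functional
# connectivity matrix.

#' SC/FC correlation
#'
#' Pearson correlation between the structural adjacency matrix and a
#' functional-connectivity matrix over all ordered off-diagonal pairs
#' (i != j). Missing FC entries (undefined correlations) are excluded
#' pairwise. A zero-variance flattened vector yields a missing coefficient
#' with an explicit status, never a silent zero.
#'
#' Because the Pearson coefficient is invariant under positive affine
#' rescaling of either argument, raw-count and normalized FC conventions give
#' identical SC/FC correlations.
#'
#' @param A adjacency matrix.
#' @param F square FC matrix of matching dimension (may contain `NA`).
#' @param symmetrize replace `F` by `(F + t(F))/2` before correlating
#'   (sensitivity option for directed sequential matrices; default off).
#' @return object of class `scfc_cor`: list with `r` (coefficient, `NA` when
#'   degenerate), `n_pairs_used`, and `status` (`"ok"` or `"degenerate"`).
#' @export
#' @examples
#' A <- make_modular(seed = 1)
#' scfc_correlation(A, A)$r # exactly 1
scfc_correlation <- function(A, F, symmetrize = FALSE) {
  A <- as_adjacency(A)
  if (!is.matrix(F) || any(dim(F) != dim(A))) {
    stop("FC matrix shape does not match the adjacency matrix", call. = FALSE)
  }
  if (symmetrize) F <- (F + t(F)) / 2
  off <- row(A) != col(A)
  a <- A[off]
  f <- F[off]
  keep <- is.finite(f)
  n_used <- sum(keep)
  out <- list(r = NA_real_, n_pairs_used = as.integer(n_used),
              status = "degenerate")
  if (n_used >= 2) {
    a <- a[keep]; f <- f[keep]
    if (stats::sd(a) > 0 && stats::sd(f) > 0) {
      out$r <- stats::cor(a, f)
      out$status <- "ok"
    }
  }
  class(out) <- "scfc_cor"
  out
}

#' @export
print.scfc_cor <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("SC/FC correlation: r = %.4f (%d off-diagonal pairs)\n",
                x$r, x$n_pairs_used))
  } else {
    cat("SC/FC correlation: undefined (degenerate flattened vectors;",
        x$n_pairs_used, "pairs available)\n")
  }
  invisible(x)
}

# sd that reports 0 (not NA) for a single observation, per the convention
# that a one-run ensemble has zero spread
sd0 <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  stats::sd(x)
}
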