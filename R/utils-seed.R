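#' Derive a reproducible child seed from a master seed
#'
#' Counter-based seed derivation used throughout the sweep drivers: every
#' (grid point, graph seed, stage) combination maps to its own child seed, so
#' sweeps are deterministic given a single master seed and remain so if grid
#' points are evaluated in any order (or in parallel).
#'
#' The scheme is a polynomial hash modulo the Mersenne prime 2^31 - 1, which
#' keeps every derived seed a valid 32-bit R integer.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices (grid index, graph seed
#'   index, stage counter, ...).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, 3, 2, 1)
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(master) %% m
  for (i in idx) {
    # 48271 is a classic MINSTD multiplier; all arithmetic stays < 2^53
    s <- (s * 48271 + as.numeric(i) + 1) %% m
  }
  as.integer(s + 1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
# If `seed` is NULL the current stream is used (and advanced).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# sample one element of x safely (sample(x, 1) misbehaves for length-1 x)
sample_one <- function(x) x[sample.int(length(x), 1L)]
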