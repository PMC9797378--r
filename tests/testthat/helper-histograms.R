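# Shared generators for property-style tests.

# n random relative-frequency histograms with K bins (Dirichlet-flat via
# normalized exponentials); some bins zeroed to exercise empty categories.
random_histograms <- function(n, K, zero_prob = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::rexp(n * K), n, K)
  zero <- matrix(stats::runif(n * K) < zero_prob, n, K)
  keep_one <- cbind(seq_len(n), sample.int(K, n, replace = TRUE))
  zero[keep_one] <- FALSE
  m[zero] <- 0
  m / rowSums(m)
}

# All compositions of `total` into K non-negative integer parts, via the
# stars-and-bars bijection; each row divided by `total` walks the
# 1/total-step frequency grid exhaustively.
frequency_grid <- function(K, step = 0.05) {
  total <- round(1 / step)
  if (K == 1L) return(matrix(1))
  bars <- t(utils::combn(total + K - 1L, K - 1L))
  n <- nrow(bars)
  counts <- matrix(0L, n, K)
  counts[, 1L] <- bars[, 1L] - 1L
  if (K > 2L) {
    counts[, 2:(K - 1L)] <- bars[, -1L, drop = FALSE] -
      bars[, -(K - 1L), drop = FALSE] - 1L
  }
  counts[, K] <- total + K - 1L - bars[, K - 1L]
  counts / total
}

# Scalar reference DFU: literal evaluation of the difference rule at one
# fixed mode position (used to cross-check the vectorized tie rule).
dfu_at_mode <- function(f, mode) {
  K <- length(f)
  d <- 0
  if (mode > 1L) d <- max(d, max(f[1:(mode - 1L)] - f[2:mode]))
  if (mode < K) d <- max(d, max(f[(mode + 1L):K] - f[mode:(K - 1L)]))
  d
}
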