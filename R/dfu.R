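#' Distance from unimodality (DFU)
#'
#' DFU measures how far an ordinal histogram f = (f1, ..., fK) is from
#' being unimodal. With m the position of the maximum frequency, the
#' difference values are
#'
#'   d_i = f_i - f_(i-1)  for i > m,
#'   d_i = f_i - f_(i+1)  for i < m,
#'   d_m = 0,
#'
#' and DFU = max(d). Every d_i is non-positive exactly when the
#' frequencies decrease monotonically away from the mode, so DFU = 0 for
#' unimodal histograms (the uniform histogram included) and DFU > 0
#' quantifies the largest adjacent-bin violation of that rule. DFU lies in
#' [0, max(f)] and is symmetric under reversing the scale.
#'
#' When several bins tie for the maximum, the deviation is evaluated at
#' every tied mode position and the smallest value is reported. This is the
#' reading most charitable toward unimodality: a plateau-topped unimodal
#' histogram scores exactly 0 regardless of which plateau bin is called the
#' mode, and the score never depends on an arbitrary argmax convention.
#'
#' @param h A [histogram()], a bare numeric frequency vector, or a numeric
#'   matrix with one histogram per row (rows are scored independently).
#'   Vectors need not sum to 1: the difference rule applies to any
#'   non-negative mass vector, so raw counts are scored on the count
#'   scale; relative frequencies give the usual [0, 1] score.
#' @return A numeric DFU score in [0, max(h)]; for matrix input, one
#'   score per row.
#' @examples
#' dfu(c(0.1, 0.2, 0.4, 0.2, 0.1))  # unimodal: 0
#' dfu(rep(0.25, 4))                # uniform: 0
#' dfu(c(0.5, 0, 0.5))              # maximally polarized on K = 3: 0.5
#' @seealso [is_unimodal()], [difference_vector()]
#' @export
dfu <- function(h) {
  m <- as_freq_matrix(h)
  K <- ncol(m)
  ld <- m[, -K, drop = FALSE] - m[, -1L, drop = FALSE]  # f_i - f_{i+1}
  rd <- m[, -1L, drop = FALSE] - m[, -K, drop = FALSE]  # f_i - f_{i-1}
  # prefix max of left differences and suffix max of right differences
  pre <- ld
  for (j in seq_len(K - 1L)[-1L]) pre[, j] <- pmax(pre[, j - 1L], ld[, j])
  suf <- rd
  for (j in rev(seq_len(K - 1L)[-(K - 1L)])) {
    suf[, j] <- pmax(suf[, j + 1L], rd[, j])
  }
  rowmax <- do.call(pmax, as.data.frame(m))
  dev_min <- rep(Inf, nrow(m))
  for (p in seq_len(K)) {
    dev <- rep(-Inf, nrow(m))
    if (p > 1L) dev <- pmax(dev, pre[, p - 1L])
    if (p < K) dev <- pmax(dev, suf[, p])
    tied <- m[, p] >= rowmax  # argmax candidates (all tied maxima)
    dev_min[tied] <- pmin(dev_min[tied], dev[tied])
  }
  unname(pmax(0, dev_min))  # d_m = 0 is always in d; clamp guards fp noise
}

#' Difference vector of a histogram around its mode
#'
#' Returns the difference values d that the DFU statistic maximizes, for a
#' single histogram, together with the mode position used. Ties for the
#' maximum frequency are broken to the leftmost position here;
#' [dfu()] itself minimizes over all tied positions, so its score can be
#' smaller than `max(difference_vector(h)$diffs)` only on tied-mode
#' histograms.
#'
#' @param h A [histogram()] or numeric frequency vector (single histogram).
#' @return A list with `mode_index` (leftmost argmax) and `diffs` (length-K
#'   numeric vector; the entry at the mode is 0).
#' @examples
#' difference_vector(c(0.2, 0.5, 0.3))
#' @export
difference_vector <- function(h) {
  m <- as_freq_matrix(h)
  if (nrow(m) != 1L)
    stop("difference_vector() takes a single histogram")
  f <- m[1L, ]
  K <- length(f)
  mode <- which.max(f)
  d <- numeric(K)
  if (mode > 1L) {
    i <- seq_len(mode - 1L)
    d[i] <- f[i] - f[i + 1L]
  }
  if (mode < K) {
    i <- (mode + 1L):K
    d[i] <- f[i] - f[i - 1L]
  }
  list(mode_index = mode, diffs = d)
}

#' Exact unimodality check for ordinal histograms
#'
#' A discrete distribution is unimodal when some position m exists such
#' that frequencies are non-decreasing up to m and non-increasing after m;
#' the uniform histogram is unimodal. The check scans every candidate mode
#' position by brute force, independently of the difference-vector route
#' used by [dfu()], and the two agree: `dfu(h) == 0` if and only if
#' `is_unimodal(h)`.
#'
#' @inheritParams dfu
#' @return Logical; for matrix input, one flag per row.
#' @examples
#' is_unimodal(c(0.1, 0.3, 0.3, 0.2))  # TRUE (plateau at the mode)
#' is_unimodal(c(0.4, 0.1, 0.5))       # FALSE (interior valley)
#' @export
is_unimodal <- function(h) {
  m <- as_freq_matrix(h)
  K <- ncol(m)
  nondec <- m[, -K, drop = FALSE] <= m[, -1L, drop = FALSE]
  noninc <- m[, -K, drop = FALSE] >= m[, -1L, drop = FALSE]
  # inc_ok[, p]: rows non-decreasing over bins 1..p; dec_ok[, p]: rows
  # non-increasing over bins p..K
  ok <- rep(FALSE, nrow(m))
  inc_ok <- rep(TRUE, nrow(m))
  dec_all <- matrix(TRUE, nrow(m), K)
  for (p in rev(seq_len(K - 1L))) {
    dec_all[, p] <- dec_all[, p + 1L] & noninc[, p]
  }
  for (p in seq_len(K)) {
    if (p > 1L) inc_ok <- inc_ok & nondec[, p - 1L]
    ok <- ok | (inc_ok & dec_all[, p])
  }
  unname(ok)
}
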