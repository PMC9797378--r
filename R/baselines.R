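#' Dispersion and consensus baselines for ordinal histograms
#'
#' The classical measures DFU is compared against. All four treat the K
#' ordered categories as integer positions 1..K and the histogram as the
#' full population distribution.
#'
#' * `stdev_dispersion()`: population standard deviation of the positions
#'   weighted by the frequencies — the go-to dispersion proxy for
#'   polarization.
#' * `leik_ordinal_dispersion()`: Leik's ordinal consensus measure
#'   D = 2 * sum(d_i) / (K - 1), where d_i folds the cumulative relative
#'   frequency F_i about one half: d_i = F_i if F_i < 0.5, else 1 - F_i.
#'   D is 0 at full consensus and 1 when mass splits 50/50 between the two
#'   extreme categories.
#' * `d2_dispersion()`: the d-squared dispersion index
#'   sum over i = 1..K-1 of (F_i - 0.5), implemented literally (it can be
#'   negative); `folded = TRUE` switches to sum |F_i - 0.5| for users who
#'   suspect the literal form dropped an absolute value.
#' * `kurtosis_peakedness()`: the fourth standardized moment of the
#'   weighted positions. The default is the Pearson convention (a normal
#'   law gives 3); `excess = TRUE` subtracts 3. Degenerate single-category
#'   histograms have zero variance and are rejected.
#'
#' @inheritParams dfu
#' @param folded For `d2_dispersion()`: fold |F_i - 0.5| instead of the
#'   literal signed sum. Off by default.
#' @param excess For `kurtosis_peakedness()`: report Fisher excess
#'   kurtosis (Pearson minus 3). Off by default.
#' @return A numeric score; for matrix input, one score per row.
#' @examples
#' h <- c(0.5, 0, 0.5)
#' stdev_dispersion(h)        # 1
#' leik_ordinal_dispersion(h) # 1
#' kurtosis_peakedness(h)     # 1 (two-point symmetric law)
#' @name baselines
NULL

#' @rdname baselines
#' @export
stdev_dispersion <- function(h) {
  m <- as_freq_matrix(h, normalize = TRUE)
  pos <- seq_len(ncol(m))
  mu <- drop(m %*% pos)
  v <- drop(m %*% pos^2) - mu^2
  unname(sqrt(pmax(v, 0)))
}

#' @rdname baselines
#' @export
leik_ordinal_dispersion <- function(h) {
  m <- as_freq_matrix(h, normalize = TRUE)
  K <- ncol(m)
  Fi <- t(apply(m, 1L, cumsum))
  if (nrow(m) == 1L) Fi <- matrix(Fi, nrow = 1L)
  d <- ifelse(Fi < 0.5, Fi, 1 - Fi)
  unname(2 * rowSums(d) / (K - 1))
}

#' @rdname baselines
#' @export
d2_dispersion <- function(h, folded = FALSE) {
  m <- as_freq_matrix(h, normalize = TRUE)
  K <- ncol(m)
  Fi <- t(apply(m, 1L, cumsum))
  if (nrow(m) == 1L) Fi <- matrix(Fi, nrow = 1L)
  dev <- Fi[, seq_len(K - 1L), drop = FALSE] - 0.5
  if (folded) dev <- abs(dev)
  unname(rowSums(dev))
}

#' @rdname baselines
#' @export
kurtosis_peakedness <- function(h, excess = FALSE) {
  m <- as_freq_matrix(h, normalize = TRUE)
  pos <- seq_len(ncol(m))
  mu <- drop(m %*% pos)
  cen <- sweep(matrix(pos, nrow(m), ncol(m), byrow = TRUE), 1L, mu)
  v <- rowSums(m * cen^2)
  if (any(v <= 0))
    stop("degenerate (single-category) histogram: kurtosis undefined ",
         "at zero variance")
  m4 <- rowSums(m * cen^4)
  k <- m4 / v^2
  unname(if (excess) k - 3 else k)
}

#' Cumulative relative frequencies of a histogram
#'
#' The running sums F_1, ..., F_K underlying Leik's D and the d-squared
#' index; F_K = 1.
#'
#' @inheritParams dfu
#' @return Numeric vector (or matrix, for matrix input) of cumulative
#'   relative frequencies.
#' @export
cumulative_frequencies <- function(h) {
  m <- as_freq_matrix(h, normalize = TRUE)
  Fi <- t(apply(m, 1L, cumsum))
  if (nrow(m) == 1L) return(drop(Fi))
  Fi
}

# Registry used by measure_comparison() and the CLI.
measure_registry <- function() {
  list(
    dfu = dfu,
    std = stdev_dispersion,
    leik = leik_ordinal_dispersion,
    d2 = d2_dispersion,
    kurtosis = kurtosis_peakedness
  )
}
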