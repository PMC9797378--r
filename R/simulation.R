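#' Gaussian-mixture specifications
#'
#' Describes a finite mixture of normal components together with the
#' sample size, number of equal-width histogram bins, and RNG seed used to
#' draw from it. The simulators stress-test DFU: samples from a unimodal
#' law should bin into histograms scoring 0, while well-separated mixtures
#' force interior valleys and positive scores.
#'
#' @param weights Numeric vector of component weights, summing to 1
#'   (tolerance 1e-9).
#' @param means Numeric vector of component means.
#' @param sds Numeric vector of positive component standard deviations.
#' @param n Sample size, >= 1.
#' @param bins Number of equal-width histogram bins, >= 2.
#' @param seed Integer RNG seed; identical specs give identical samples.
#' @return An object of class `mixture_spec`.
#' @examples
#' mixture_spec(1, 0, 1, n = 1000, bins = 10, seed = 7)
#' mixture_preset("bimodal")
#' @export
mixture_spec <- function(weights, means, sds, n = 10000L, bins = 10L,
                         seed = 1L) {
  weights <- as.numeric(weights); means <- as.numeric(means)
  sds <- as.numeric(sds)
  k <- length(weights)
  if (k < 1L || length(means) != k || length(sds) != k)
    stop("weights, means and sds must have equal positive length")
  if (anyNA(c(weights, means, sds)))
    stop("mixture components must not contain missing values")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9)
    stop("weights must be non-negative and sum to 1")
  if (any(sds <= 0)) stop("sds must be positive")
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  if (!is.numeric(bins) || bins < 2) stop("bins must be >= 2")
  structure(list(weights = weights, means = means, sds = sds,
                 n = as.integer(n), bins = as.integer(bins),
                 seed = as.integer(seed)),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat("Gaussian mixture: ", length(x$weights), " component(s); n = ", x$n,
      ", bins = ", x$bins, ", seed = ", x$seed, "\n", sep = "")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' @rdname mixture_spec
#' @param preset One of `"unimodal"` (unit normal), `"bimodal"` (two
#'   components with standard deviations 3 and 10) or `"trimodal"` (three
#'   components with standard deviations 5, 5 and 10). Component means and
#'   weights are this package's own choices, picked so that the bimodal
#'   and trimodal presets produce clearly multimodal 10-bin histograms.
#' @param ... Overrides for `n`, `bins`, `seed`.
#' @export
mixture_preset <- function(preset = c("unimodal", "bimodal", "trimodal"),
                           ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    unimodal = list(weights = 1, means = 0, sds = 1),
    bimodal  = list(weights = c(0.5, 0.5), means = c(-12, 12),
                    sds = c(3, 10)),
    trimodal = list(weights = c(1, 1, 1) / 3, means = c(-25, 0, 30),
                    sds = c(5, 5, 10)))
  do.call(mixture_spec, c(args, list(...)))
}

#' Draw from a Gaussian mixture
#'
#' Each draw picks a component by weight, then samples from that normal.
#' Fully reproducible under the spec's seed.
#'
#' @param spec A [mixture_spec()].
#' @return Numeric vector of `spec$n` draws.
#' @export
sample_mixture <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  withr::local_seed(spec$seed)
  comp <- sample.int(length(spec$weights), spec$n, replace = TRUE,
                     prob = spec$weights)
  stats::rnorm(spec$n, mean = spec$means[comp], sd = spec$sds[comp])
}

#' Bin a mixture sample into an ordinal histogram
#'
#' Draws the sample, then bins it into `spec$bins` equal-width, right-open
#' bins (the last bin closed) spanning the sample range, or `range` when
#' given. Each bin is one ordinal category, so the result feeds directly
#' into [dfu()] and the baselines.
#'
#' @param spec A [mixture_spec()].
#' @param range Optional length-2 numeric fixed binning interval; default
#'   is the sample range.
#' @return A [histogram()].
#' @examples
#' h <- mixture_histogram(mixture_preset("unimodal", seed = 7))
#' dfu(h)  # 0: a unit normal bins into a unimodal histogram
#' @export
mixture_histogram <- function(spec, range = NULL) {
  x <- sample_mixture(spec)
  if (is.null(range)) range <- base::range(x)
  if (diff(range) <= 0)
    stop("zero-width range: all samples identical, cannot bin")
  breaks <- seq(range[1L], range[2L], length.out = spec$bins + 1L)
  idx <- findInterval(x, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(idx, nbins = spec$bins)
  histogram(counts, counts = TRUE)
}
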