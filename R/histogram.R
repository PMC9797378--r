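#' Ordinal histograms
#'
#' A histogram is the vector of relative frequencies f = (f1, ..., fK) of
#' the K categories of an ordinal scale; it is the object the DFU statistic
#' and the dispersion baselines consume. Frequencies must be non-negative
#' and sum to 1 (tolerance 1e-9). Zero bins are legal and are never
#' smoothed.
#'
#' @param freqs Numeric vector of K relative frequencies, lowest category
#'   first. Raw counts are accepted with `counts = TRUE` and normalized.
#' @param scale Optional [ordinal_scale()]; defaults to an anonymous scale
#'   `O1 < ... < OK` matching the length of `freqs`.
#' @param counts If `TRUE`, `freqs` are non-negative counts and are divided
#'   by their total.
#' @return An object of class `dfu_histogram`: a numeric vector of
#'   frequencies with the scale attached.
#' @examples
#' histogram(c(0.5, 0, 0.5))
#' histogram(c(4, 0, 4), counts = TRUE)
#' @export
histogram <- function(freqs, scale = NULL, counts = FALSE) {
  freqs <- as.numeric(freqs)
  if (length(freqs) < 2L)
    stop("a histogram needs at least 2 bins, got ", length(freqs))
  if (anyNA(freqs))
    stop("histogram frequencies must not be missing")
  if (any(freqs < 0))
    stop("histogram frequencies must be non-negative")
  if (counts) {
    tot <- sum(freqs)
    if (tot <= 0) stop("counts sum to zero; empty histogram")
    freqs <- freqs / tot
  } else if (abs(sum(freqs) - 1) > 1e-9) {
    stop("relative frequencies must sum to 1 (got ", format(sum(freqs)),
         "); use counts = TRUE for raw counts")
  }
  if (is.null(scale)) {
    scale <- ordinal_scale(paste0("O", seq_along(freqs)))
  }
  stopifnot(inherits(scale, "ordinal_scale"))
  if (length(freqs) != scale$K)
    stop("histogram has ", length(freqs), " bins but the scale has ",
         scale$K, " categories")
  structure(as.numeric(freqs), names = scale$labels, scale = scale,
            class = "dfu_histogram")
}

#' @export
print.dfu_histogram <- function(x, digits = 4, ...) {
  cat("Ordinal histogram (K = ", attr(x, "scale")$K, ")\n", sep = "")
  print(round(stats::setNames(as.numeric(x), names(x)), digits))
  invisible(x)
}

#' Build a histogram from raw ordinal labels
#'
#' Counts each observed label against the categories of `scale` and returns
#' the relative-frequency histogram. Categories that never occur get
#' frequency zero.
#'
#' @param labels Character vector of observed ratings; every value must be
#'   a category of `scale`.
#' @param scale An [ordinal_scale()].
#' @return A `dfu_histogram`.
#' @examples
#' build_histogram(c("neg", "neg", "pos", "pos"),
#'                 ordinal_scale(c("neg", "neu", "pos")))
#' @export
build_histogram <- function(labels, scale) {
  stopifnot(inherits(scale, "ordinal_scale"))
  labels <- as.character(labels)
  if (length(labels) == 0L)
    stop("no labels supplied; cannot build a histogram from empty input")
  bad <- setdiff(unique(labels), scale$labels)
  if (length(bad) > 0L)
    stop("label not on the scale: ", paste(dQuote(bad), collapse = ", "))
  counts <- table(factor(labels, levels = scale$labels))
  histogram(as.numeric(counts), scale = scale, counts = TRUE)
}

# Coerce plain numeric input to a frequency matrix with one histogram per
# row, validating each row. Shared by dfu(), is_unimodal() and the
# baselines so they all accept a histogram, a bare frequency vector, or a
# matrix of histograms. The difference rule behind DFU is scale-free in
# the sense of being computable on raw counts, so rows are taken as given
# unless `normalize` is set; measures built on cumulative relative
# frequencies (Leik, d-squared) need normalize = TRUE.
as_freq_matrix <- function(h, normalize = FALSE) {
  if (inherits(h, "dfu_histogram")) {
    m <- matrix(as.numeric(h), nrow = 1L)
  } else if (is.matrix(h)) {
    m <- h
  } else if (is.numeric(h)) {
    m <- matrix(as.numeric(h), nrow = 1L)
  } else {
    stop("expected a histogram, a numeric frequency vector, or a matrix")
  }
  if (ncol(m) < 2L) stop("histograms need at least 2 bins")
  if (anyNA(m) || any(m < 0))
    stop("histogram frequencies must be non-negative and non-missing")
  s <- rowSums(m)
  if (any(s <= 0))
    stop("row ", which(s <= 0)[1L], ": histogram has no mass")
  if (normalize) m <- m / s
  m
}

#' Serialize histograms to and from JSON and CSV
#'
#' JSON uses `{"scale": [...], "freqs": [...]}`; CSV uses one row per
#' histogram with columns `f1..fK` (and any leading id columns preserved).
#'
#' @param h A `dfu_histogram`.
#' @param path File path.
#' @return Readers return a `dfu_histogram` (JSON) or a `tibble` with a
#'   numeric matrix column layout `f1..fK` (CSV); writers return `path`
#'   invisibly.
#' @export
write_histogram_json <- function(h, path) {
  stopifnot(inherits(h, "dfu_histogram"))
  jsonlite::write_json(
    list(scale = attr(h, "scale")$labels, freqs = as.numeric(h)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_histogram_json
#' @export
read_histogram_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$freqs)) stop("JSON file ", path, " has no 'freqs' field")
  sc <- if (is.null(x$scale)) NULL else ordinal_scale(x$scale)
  histogram(x$freqs, scale = sc)
}

#' @rdname write_histogram_json
#' @export
read_histograms_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  if (length(fcols) < 2L)
    stop("CSV ", path, " needs frequency columns f1..fK")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  tibble::as_tibble(df[, c(setdiff(names(df), fcols), fcols)])
}

# Extract the f1..fK block of a histogram table as a matrix.
freq_cols_matrix <- function(df) {
  fcols <- grep("^f[0-9]+$", names(df), value = TRUE)
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  as.matrix(df[, fcols, drop = FALSE])
}
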