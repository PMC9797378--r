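#' Ordinal rating scales
#'
#' An ordinal scale is a finite, totally ordered set of K >= 2 rating
#' categories (e.g., negative < neutral < positive). The order of `labels`
#' is the order of the scale; it is fixed at construction.
#'
#' @param labels Character vector of K >= 2 unique category names, from the
#'   lowest to the highest category.
#' @return An object of class `ordinal_scale`.
#' @examples
#' ordinal_scale(c("negative", "neutral", "positive"))
#' toxicity_scale()
#' @export
ordinal_scale <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("an ordinal scale needs at least 2 categories, got ", length(labels))
  if (anyNA(labels) || any(!nzchar(labels)))
    stop("scale labels must be non-missing, non-empty strings")
  if (anyDuplicated(labels))
    stop("duplicate scale label: ", labels[duplicated(labels)][1L])
  structure(list(labels = labels, K = length(labels)), class = "ordinal_scale")
}

#' @export
print.ordinal_scale <- function(x, ...) {
  cat("Ordinal scale (K = ", x$K, "): ",
      paste(x$labels, collapse = " < "), "\n", sep = "")
  invisible(x)
}

#' @export
length.ordinal_scale <- function(x) x$K

#' @rdname ordinal_scale
#' @details `sentiment_scale()` is the 3-class valence scale used when
#'   discretizing continuous sentiment scores; `toxicity_scale()` is the
#'   default 4-level crowd-toxicity scale. "hard to say" is placed between
#'   "not toxic" and "toxic" as a middle judgment; pass your own
#'   [ordinal_scale()] to override.
#' @export
sentiment_scale <- function() {
  ordinal_scale(c("negative", "neutral", "positive"))
}

#' @rdname ordinal_scale
#' @export
toxicity_scale <- function() {
  ordinal_scale(c("not toxic", "hard to say", "toxic", "very toxic"))
}

#' Read or write an ordinal scale definition file
#'
#' Scale files are YAML (or JSON) with a single `labels` key listing the
#' categories in order, so that category sets live in configuration rather
#' than code.
#'
#' @param path File path.
#' @param scale An `ordinal_scale`.
#' @return `read_scale()` returns an `ordinal_scale`; `write_scale()`
#'   returns `path` invisibly.
#' @export
read_scale <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$labels))
    stop("scale file ", path, " has no 'labels' key")
  ordinal_scale(unlist(x$labels))
}

#' @rdname read_scale
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "ordinal_scale"))
  yaml::write_yaml(list(labels = as.list(scale$labels)), path)
  invisible(path)
}
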