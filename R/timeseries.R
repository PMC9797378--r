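#' Discretize continuous sentiment scores into ordinal valence classes
#'
#' Valence scores live in [0, 1], 0 = very negative, 1 = very positive.
#' A score is `positive` when strictly above `pos_threshold`, `negative`
#' when strictly below `neg_threshold`, and `neutral` otherwise — boundary
#' scores are neutral. The default thresholds (0.61, 0.43) are the
#' operating points of the sentiment model the valence convention comes
#' from.
#'
#' @param score Numeric vector of scores in [0, 1].
#' @param pos_threshold Scores strictly above this are positive.
#' @param neg_threshold Scores strictly below this are negative; must be
#'   below `pos_threshold`.
#' @return A factor with ordered levels negative < neutral < positive.
#' @examples
#' discretize_sentiment(c(0.62, 0.42, 0.43, 0.61))
#' @export
discretize_sentiment <- function(score, pos_threshold = 0.61,
                                 neg_threshold = 0.43) {
  if (!is.numeric(score) || anyNA(score))
    stop("scores must be numeric and non-missing")
  if (any(score < 0 | score > 1))
    stop("scores must lie in [0, 1]; offending value: ",
         score[score < 0 | score > 1][1L])
  if (!(neg_threshold < pos_threshold))
    stop("neg_threshold must be below pos_threshold")
  cls <- ifelse(score > pos_threshold, "positive",
                ifelse(score < neg_threshold, "negative", "neutral"))
  factor(cls, levels = sentiment_scale()$labels)
}

#' Per-cluster polarization of sentiment-scored items
#'
#' Groups scored items by `(date, region)`, discretizes their scores into
#' negative/neutral/positive, builds the 3-bin valence histogram per
#' cluster and computes its DFU. A cluster is flagged as a peak (a
#' polarized day) when DFU exceeds `peak_threshold` — strictly greater
#' than 0 by default, so any departure from unimodality counts.
#'
#' @param items Data frame with columns `item_id`, `date`, `region`,
#'   `score`. Dates are kept as the strings given (ISO 8601 recommended);
#'   no timezone arithmetic is performed.
#' @param pos_threshold,neg_threshold Passed to [discretize_sentiment()].
#' @param peak_threshold Clusters with DFU strictly above this are peaks.
#' @return A tibble sorted by `(date, region)` with columns `date`,
#'   `region`, `n`, `f_neg`, `f_neu`, `f_pos`, `dfu`, `peak`, carrying
#'   attributes `n_unimodal` (clusters with DFU = 0) and `n_peaks`.
#' @examples
#' x <- data.frame(item_id = 1:4, date = "2020-06-06", region = "NY",
#'                 score = c(0.1, 0.9, 0.12, 0.88))
#' cluster_polarization(x)
#' @export
cluster_polarization <- function(items, pos_threshold = 0.61,
                                 neg_threshold = 0.43,
                                 peak_threshold = 0) {
  items <- as.data.frame(items)
  need <- c("item_id", "date", "region", "score")
  miss <- setdiff(need, names(items))
  if (length(miss) > 0L)
    stop("items are missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(items) == 0L) stop("no scored items supplied")
  items$class <- discretize_sentiment(items$score, pos_threshold,
                                      neg_threshold)
  out <- items |>
    dplyr::group_by(date = as.character(date),
                    region = as.character(region)) |>
    dplyr::summarise(
      n = dplyr::n(),
      f_neg = mean(class == "negative"),
      f_neu = mean(class == "neutral"),
      f_pos = mean(class == "positive"),
      .groups = "drop") |>
    dplyr::arrange(date, region)
  out$dfu <- dfu(as.matrix(out[, c("f_neg", "f_neu", "f_pos")]))
  out$peak <- out$dfu > peak_threshold
  attr(out, "n_unimodal") <- sum(out$dfu == 0)
  attr(out, "n_peaks") <- sum(out$peak)
  out
}

#' Mean raw sentiment per cluster
#'
#' Arithmetic mean of the un-discretized valence scores per
#' `(date, region)` cluster — the smooth daily-sentiment companion to the
#' DFU peak series.
#'
#' @inheritParams cluster_polarization
#' @return A tibble with columns `date`, `region`, `n`, `mean_score`.
#' @export
daily_mean_sentiment <- function(items) {
  items <- as.data.frame(items)
  need <- c("date", "region", "score")
  miss <- setdiff(need, names(items))
  if (length(miss) > 0L)
    stop("items are missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(items) == 0L) stop("no scored items supplied")
  items |>
    dplyr::group_by(date = as.character(date),
                    region = as.character(region)) |>
    dplyr::summarise(n = dplyr::n(), mean_score = mean(score),
                     .groups = "drop") |>
    dplyr::arrange(date, region)
}
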