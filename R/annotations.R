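#' Aggregate multi-rater ordinal annotations into per-item DFU scores
#'
#' Takes one row per judgment (`item_id`, `rater_id`, `label`, optional
#' `country`) and produces one row per item with its rating histogram, DFU
#' score, rater count and the number of distinct rater countries. Items
#' whose annotations split into opposing clusters score DFU > 0; items
#' with consensus or graded disagreement score 0.
#'
#' @param records Data frame of annotation records with columns `item_id`,
#'   `rater_id`, `label` and optionally `country`. Missing countries are
#'   excluded from the distinct-country count, never imputed. Duplicate
#'   (item_id, rater_id) pairs are legal but flagged with a warning.
#' @param scale An [ordinal_scale()]; every label must be one of its
#'   categories.
#' @return A tibble with columns `item_id`, `n_raters`, `f1..fK` (the
#'   relative-frequency histogram on `scale`), `dfu` and `n_countries`.
#' @examples
#' rec <- data.frame(item_id = "a", rater_id = 1:4,
#'                   label = c("not toxic", "not toxic",
#'                             "very toxic", "very toxic"))
#' aggregate_annotations(rec, toxicity_scale())
#' @export
aggregate_annotations <- function(records, scale) {
  stopifnot(inherits(scale, "ordinal_scale"))
  records <- as.data.frame(records)
  need <- c("item_id", "rater_id", "label")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0L)
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no annotation records supplied")
  bad <- !(records$label %in% scale$labels)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop("item ", dQuote(records$item_id[i]), ": label ",
         dQuote(records$label[i]), " is not on the scale")
  }
  dup <- duplicated(records[, c("item_id", "rater_id")])
  if (any(dup))
    warning(sum(dup), " duplicate (item_id, rater_id) judgment(s) kept")
  if (!"country" %in% names(records)) records$country <- NA_character_

  lab <- factor(records$label, levels = scale$labels)
  counts <- table(records$item_id, lab)         # items x K
  fm <- counts / rowSums(counts)
  fm <- matrix(as.numeric(fm), nrow = nrow(counts),
               dimnames = dimnames(counts))
  n_countries <- vapply(
    split(records$country, records$item_id),
    function(x) length(unique(x[!is.na(x) & nzchar(x)])), integer(1L))

  out <- tibble::tibble(
    item_id = rownames(counts),
    n_raters = as.integer(rowSums(counts)),
    dfu = dfu(fm),
    n_countries = unname(n_countries[rownames(counts)]))
  freq <- tibble::as_tibble(as.data.frame(fm))
  names(freq) <- paste0("f", seq_len(scale$K))
  dplyr::bind_cols(out[, c("item_id", "n_raters")], freq,
                   out[, c("dfu", "n_countries")])
}

#' Resample high- vs low-DFU items and compare rater-country diversity
#'
#' Splits items at the q-th quantile of their DFU scores (items exactly at
#' the quantile fall on the low side), then repeatedly draws
#' `sample_size` items without replacement from each side and compares the
#' mean number of distinct rater countries. A repetition is a success when
#' the high-DFU sample's mean is strictly larger. A one-sided sign-test
#' p-value over the repetitions is reported as supporting evidence.
#'
#' @param table Output of [aggregate_annotations()] (needs columns `dfu`
#'   and `n_countries`).
#' @param quantile Probability for the DFU split; default 0.75 (the third
#'   quartile).
#' @param sample_size Items drawn per side per repetition; clamped (with a
#'   warning) to the smaller side when a side has fewer items.
#' @param repetitions Number of resampling repetitions.
#' @param seed Integer master seed; repetitions are independent draws from
#'   one seeded stream.
#' @return A list of class `dfu_resampling` with `repetitions`,
#'   `successes`, `mean_high`, `mean_low` (grand means over repetitions),
#'   `sign_test_p`, `sample_size`, `quantile_value` and `seed`.
#' @examples
#' rec <- generate_synthetic_annotations(400, 6, polarized_fraction = 0.25,
#'                                       country_effect = TRUE, seed = 3)
#' tab <- aggregate_annotations(rec, toxicity_scale())
#' country_diversity_resampling(tab, sample_size = 50, repetitions = 20,
#'                              seed = 3)
#' @export
country_diversity_resampling <- function(table, quantile = 0.75,
                                         sample_size = 1000L,
                                         repetitions = 100L, seed = 1L) {
  if (!all(c("dfu", "n_countries") %in% names(table)))
    stop("table needs 'dfu' and 'n_countries' columns; run ",
         "aggregate_annotations() first")
  qv <- stats::quantile(table$dfu, probs = quantile, names = FALSE)
  hi <- which(table$dfu > qv)
  lo <- which(table$dfu <= qv)
  if (length(hi) == 0L || length(lo) == 0L)
    stop("degenerate quantile split: all DFU values fall on one side")
  avail <- min(length(hi), length(lo))
  if (sample_size > avail) {
    warning("sample_size lowered from ", sample_size, " to ", avail,
            " (smaller side of the DFU split)")
    sample_size <- avail
  }
  withr::local_seed(seed)
  mh <- ml <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    mh[r] <- mean(table$n_countries[sample(hi, sample_size)])
    ml[r] <- mean(table$n_countries[sample(lo, sample_size)])
  }
  successes <- sum(mh > ml)
  p <- stats::binom.test(successes, repetitions,
                         alternative = "greater")$p.value
  structure(list(repetitions = as.integer(repetitions),
                 successes = as.integer(successes),
                 mean_high = mean(mh), mean_low = mean(ml),
                 sign_test_p = p, sample_size = as.integer(sample_size),
                 quantile_value = qv, seed = as.integer(seed)),
            class = "dfu_resampling")
}

#' @export
print.dfu_resampling <- function(x, ...) {
  cat("Country-diversity resampling over ", x$repetitions,
      " repetitions (", x$sample_size, " items/side, DFU split at ",
      format(x$quantile_value, digits = 4), ")\n", sep = "")
  cat("  high-DFU mean countries > low-DFU mean countries in ",
      x$successes, "/", x$repetitions, " repetitions\n", sep = "")
  cat("  grand means: high ", format(x$mean_high, digits = 4), ", low ",
      format(x$mean_low, digits = 4), "; one-sided sign-test p = ",
      format(x$sign_test_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic multi-rater annotation corpus
#'
#' Stands in for a large crowd-annotated toxicity corpus. A
#' `polarized_fraction` share of items receives labels split (with a
#' random imbalance, both sides non-empty) between the two extreme
#' categories of the scale, which forces a bimodal histogram and
#' DFU > 0. The remaining
#' items receive a majority label on a random category with at most a
#' minority of adjacent-category dissent on one side, which keeps the
#' histogram monotone and forces DFU = 0. With `country_effect` on,
#' raters of polarized items are drawn from a larger country pool
#' (10 countries vs 3), creating the diversity signal that
#' [country_diversity_resampling()] detects; with it off, all raters share
#' one 5-country pool and the resampling is null-calibrated.
#'
#' @param n_items Number of items, >= 1.
#' @param raters_per_item Raters per item, >= 2.
#' @param polarized_fraction Probability that an item is polarized.
#' @param country_effect Couple country diversity to polarization?
#' @param seed Integer seed; identical arguments give identical corpora.
#' @param scale An [ordinal_scale()] with K >= 3 (the extremes must be
#'   non-adjacent for a guaranteed valley); default [toxicity_scale()].
#' @return A tibble of annotation records (`item_id`, `rater_id`, `label`,
#'   `country`).
#' @export
generate_synthetic_annotations <- function(n_items, raters_per_item,
                                           polarized_fraction = 0.25,
                                           country_effect = FALSE,
                                           seed = 1L,
                                           scale = toxicity_scale()) {
  if (!is.numeric(n_items) || n_items < 1)
    stop("n_items must be >= 1")
  if (!is.numeric(raters_per_item) || raters_per_item < 2)
    stop("raters_per_item must be >= 2")
  if (!is.numeric(polarized_fraction) || polarized_fraction < 0 ||
      polarized_fraction > 1)
    stop("polarized_fraction must be a probability")
  stopifnot(inherits(scale, "ordinal_scale"))
  if (scale$K < 3L)
    stop("scale needs K >= 3 so the extreme categories are non-adjacent")
  n_items <- as.integer(n_items)
  r <- as.integer(raters_per_item)
  withr::local_seed(seed)

  pool_small <- paste0("C", 1:3)
  pool_large <- paste0("C", 1:10)
  pool_null <- paste0("C", 1:5)

  polarized <- stats::runif(n_items) < polarized_fraction
  lab_list <- vector("list", n_items)
  ctry_list <- vector("list", n_items)
  K <- scale$K
  for (i in seq_len(n_items)) {
    if (polarized[i]) {
      # random imbalance with both extremes represented: DFU = the
      # smaller extreme's share, so polarized items spread over
      # (0, 1/2] instead of piling up on one value
      n_low <- sample.int(r - 1L, 1L)
      lab <- c(rep(scale$labels[1L], n_low),
               rep(scale$labels[K], r - n_low))
      lab_list[[i]] <- sample(lab)
      pool <- if (country_effect) pool_large else pool_null
    } else {
      mode <- sample.int(K, 1L)
      n_dissent <- stats::rbinom(1L, max((r - 1L) %/% 2L, 0L), 0.3)
      side <- if (mode == 1L) mode + 1L
              else if (mode == K) mode - 1L
              else mode + sample(c(-1L, 1L), 1L)
      lab_list[[i]] <- sample(c(rep(scale$labels[mode], r - n_dissent),
                                rep(scale$labels[side], n_dissent)))
      pool <- if (country_effect) pool_small else pool_null
    }
    ctry_list[[i]] <- sample(pool, r, replace = TRUE)
  }
  tibble::tibble(
    item_id = rep(sprintf("item%05d", seq_len(n_items)), each = r),
    rater_id = rep(paste0("r", seq_len(r)), times = n_items),
    label = unlist(lab_list),
    country = unlist(ctry_list))
}

#' Read and write annotation record CSV files
#'
#' One row per judgment; columns `item_id`, `rater_id`, `label`, optional
#' `country`; UTF-8 with a header.
#'
#' @param path File path.
#' @param records A data frame of annotation records.
#' @return `read_annotations_csv()` returns a tibble; the writer returns
#'   `path` invisibly.
#' @export
read_annotations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "rater_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("annotation CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  tibble::as_tibble(df)
}

#' @rdname read_annotations_csv
#' @export
write_annotations_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
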