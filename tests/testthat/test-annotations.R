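scale4 <- toxicity_scale()

test_that("aggregate_annotations builds one scored row per item", {
  rec <- data.frame(
    item_id = c(rep("a", 3), rep("b", 2)),
    rater_id = c("r1", "r2", "r3", "r1", "r2"),
    label = c(rep("not toxic", 3), "not toxic", "very toxic"),
    country = c("GR", "SE", NA, "GR", "GR"))
  tab <- aggregate_annotations(rec, scale4)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$n_raters, c(3L, 2L))
  expect_equal(tab$dfu[tab$item_id == "a"], 0)        # full consensus
  expect_equal(tab$dfu[tab$item_id == "b"], 0.5)      # extreme 50/50
  expect_equal(tab$n_countries, c(2L, 1L))            # NA country excluded
  expect_equal(unname(unlist(tab[tab$item_id == "b",
                                 paste0("f", 1:4)])),
               c(0.5, 0, 0, 0.5))
})

test_that("aggregation rejects unknown labels and flags duplicates", {
  bad <- data.frame(item_id = "a", rater_id = "r1", label = "meh")
  expect_error(aggregate_annotations(bad, scale4), "meh")
  expect_error(aggregate_annotations(bad[0, ], scale4), "no annotation")
  dup <- data.frame(item_id = "a", rater_id = c("r1", "r1"),
                    label = rep("toxic", 2))
  expect_warning(aggregate_annotations(dup, scale4), "duplicate")
})

test_that("aggregation is invariant to record order", {
  rec <- generate_synthetic_annotations(50, 5, polarized_fraction = 0.4,
                                        seed = 21)
  tab1 <- aggregate_annotations(rec, scale4)
  tab2 <- aggregate_annotations(rec[sample.int(nrow(rec)), ], scale4)
  expect_equal(tab1, tab2)
})

test_that("the synthetic corpus hits its polarization construction", {
  # every polarized item bimodal, every unpolarized item unimodal
  all_pol <- aggregate_annotations(
    generate_synthetic_annotations(100, 6, polarized_fraction = 1,
                                   seed = 31), scale4)
  expect_true(all(all_pol$dfu > 0))
  none_pol <- aggregate_annotations(
    generate_synthetic_annotations(100, 6, polarized_fraction = 0,
                                   seed = 32), scale4)
  expect_true(all(none_pol$dfu == 0))
  # odd rater counts still split across both extremes
  odd <- aggregate_annotations(
    generate_synthetic_annotations(100, 5, polarized_fraction = 1,
                                   seed = 33), scale4)
  expect_true(all(odd$dfu > 0))
  # same seed, same corpus
  expect_identical(
    generate_synthetic_annotations(40, 4, seed = 34),
    generate_synthetic_annotations(40, 4, seed = 34))
  expect_error(generate_synthetic_annotations(0, 5), "n_items")
  expect_error(generate_synthetic_annotations(5, 1), "raters_per_item")
  expect_error(generate_synthetic_annotations(5, 5, polarized_fraction = 2),
               "probability")
})

test_that("the zero-DFU share tracks 1 - polarized_fraction", {
  tab <- aggregate_annotations(
    generate_synthetic_annotations(2000, 6, polarized_fraction = 0.34,
                                   seed = 41), scale4)
  expect_equal(mean(tab$dfu == 0), 0.66, tolerance = 0.05)
})

test_that("country resampling detects the planted diversity effect", {
  tab <- aggregate_annotations(
    generate_synthetic_annotations(1500, 6, polarized_fraction = 0.25,
                                   country_effect = TRUE, seed = 51),
    scale4)
  res <- country_diversity_resampling(tab, sample_size = 150,
                                      repetitions = 50, seed = 52)
  expect_equal(res$successes, res$repetitions)
  expect_gt(res$mean_high, res$mean_low)
  expect_lt(res$sign_test_p, 0.001)
  # one repetition checked by brute force: means over full sides differ
  expect_gt(mean(tab$n_countries[tab$dfu > res$quantile_value]),
            mean(tab$n_countries[tab$dfu <= res$quantile_value]))
})

test_that("resampling clamps oversized samples and rejects degenerate splits", {
  tab <- aggregate_annotations(
    generate_synthetic_annotations(200, 6, polarized_fraction = 0.25,
                                   seed = 61), scale4)
  expect_warning(
    res <- country_diversity_resampling(tab, sample_size = 5000,
                                        repetitions = 5, seed = 62),
    "lowered")
  expect_lte(res$sample_size, min(sum(tab$dfu > res$quantile_value),
                                  sum(tab$dfu <= res$quantile_value)))
  flat <- tab
  flat$dfu <- 0
  expect_error(country_diversity_resampling(flat, seed = 1), "degenerate")
  expect_error(country_diversity_resampling(data.frame(x = 1)),
               "n_countries")
})

test_that("annotation CSV round-trips", {
  rec <- generate_synthetic_annotations(20, 3, seed = 71)
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations_csv(rec, f)
  back <- read_annotations_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines("item_id,whatever\na,1", g)
  expect_error(read_annotations_csv(g), "missing column")
})
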