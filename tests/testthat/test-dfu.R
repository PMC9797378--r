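test_that("dfu reproduces the worked examples", {
  expect_equal(dfu(c(0.1, 0.2, 0.4, 0.2, 0.1)), 0)     # unimodal
  expect_equal(dfu(rep(0.25, 4)), 0)                   # uniform
  expect_equal(dfu(c(0.5, 0, 0.5)), 0.5)               # extreme split
  expect_equal(dfu(c(0.4, 0.1, 0.4, 0.35)), 0.3, tolerance = 1e-12)
  expect_equal(dfu(c(0.2, 0.5, 0.3)), 0)
  expect_equal(dfu(histogram(c(0.5, 0, 0.5))), 0.5)
})

test_that("difference_vector matches hand evaluation of the rule", {
  dv <- difference_vector(c(0.2, 0.5, 0.3))
  expect_equal(dv$mode_index, 2L)
  expect_equal(dv$diffs, c(-0.3, 0, -0.2))
  # leftmost tie: mode at 1, right-side difference exposes the far spike
  dv2 <- difference_vector(c(0.5, 0, 0.5))
  expect_equal(dv2$mode_index, 1L)
  expect_equal(dv2$diffs[3], 0.5)
  # uniform: all differences vanish by definition
  expect_equal(difference_vector(rep(0.2, 5))$diffs, rep(0, 5))
  expect_error(difference_vector(rbind(c(0.5, 0.5), c(0.5, 0.5))),
               "single histogram")
})

test_that("is_unimodal brute-force matches its definition", {
  expect_true(is_unimodal(c(0.1, 0.3, 0.3, 0.2)))   # plateau mode
  expect_false(is_unimodal(c(0.4, 0.1, 0.5)))       # interior valley
  expect_true(is_unimodal(rep(1 / 6, 6)))           # uniform is unimodal
  expect_true(is_unimodal(c(0.05, 0.2, 0.75)))      # monotone increase
  expect_true(is_unimodal(c(0.75, 0.2, 0.05)))      # monotone decrease
})

test_that("dfu = 0 exactly when the histogram is unimodal (grid, K <= 5)", {
  for (K in 2:5) {
    g <- frequency_grid(K, step = 0.1)
    expect_identical(dfu(g) == 0, is_unimodal(g),
                     label = paste0("K=", K, " grid"))
  }
})

test_that("dfu is reversal-symmetric and bounded by the modal mass", {
  set.seed(421)
  for (K in c(3L, 5L, 8L)) {
    f <- random_histograms(300, K)
    s <- dfu(f)
    expect_equal(dfu(f[, K:1, drop = FALSE]), s)
    expect_true(all(s >= 0))
    expect_true(all(s <= apply(f, 1L, max) + 1e-12))
  }
})

test_that("tied maxima score the minimum deviation over tied modes", {
  set.seed(77)
  for (rep in 1:200) {
    K <- sample(3:7, 1L)
    f <- as.vector(random_histograms(1, K))
    # force a tie between two random positions
    ij <- sample.int(K, 2L)
    f[ij] <- max(f) + 0.1
    f <- f / sum(f)
    tied <- which(f >= max(f) - 1e-12)
    ref <- min(vapply(tied, function(m) dfu_at_mode(f, m), numeric(1)))
    expect_equal(dfu(f), max(0, ref), tolerance = 1e-12)
  }
  # the tie-minimum can undercut the leftmost-argmax convention, but
  # never exceed it
  set.seed(78)
  f <- random_histograms(500, 6)
  left <- vapply(seq_len(nrow(f)), function(i) {
    max(0, dfu_at_mode(f[i, ], which.max(f[i, ])))
  }, numeric(1))
  expect_true(all(dfu(f) <= left + 1e-12))
})

test_that("sharpening the mode never increases dfu", {
  # Moving mass from a mode-adjacent bin onto the mode cannot raise the
  # score, provided the drained bin is not pushed below its outward
  # neighbour (draining it further can open a fresh valley and raise
  # DFU, e.g. (0.3, 0.35, 0.3, 0.05) with bin 3 emptied onto the mode).
  set.seed(99)
  for (rep in 1:200) {
    K <- sample(3:7, 1L)
    f <- as.vector(random_histograms(1, K, zero_prob = 0))
    m <- which.max(f)
    nb <- if (m == 1L) 2L else if (m == K) K - 1L else
      m + sample(c(-1L, 1L), 1L)
    beyond <- nb + (nb - m)  # next bin outward from the mode, if any
    cap <- if (beyond >= 1L && beyond <= K) max(0, f[nb] - f[beyond])
           else f[nb]
    eps <- stats::runif(1, 0, cap)
    g <- f
    g[nb] <- g[nb] - eps
    g[m] <- g[m] + eps
    expect_lte(dfu(g), dfu(f) + 1e-12)
  }
})

test_that("raw counts score on the count scale, consistently with freqs", {
  cnt <- c(4, 0, 4)
  expect_equal(dfu(cnt), 4)
  expect_equal(dfu(cnt / sum(cnt)), 0.5)
  expect_error(dfu(c(-1, 2)), "non-negative")
  expect_error(dfu(c(0, 0)), "no mass")
})
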