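test_that("moment summary is exact on large Gaussian samples", {
  set.seed(1)
  s <- distance_sequence(rnorm(1e4, 50, 5))
  sm <- summarize_distances(s)
  expect_equal(sm$skewness, 0, tolerance = 0.05)
  expect_equal(sm$kurtosis, 0, tolerance = 0.1)
  expect_equal(sm$n, 1e4)
  expect_error(summarize_distances(distance_sequence(rep(10, 20))),
               "degenerate")
  expect_error(summarize_distances(distance_sequence(1:5)), "at least 8")
})

test_that("histogram bins are zero-anchored, left-closed and normalized", {
  s <- distance_sequence(c(2, 7, 7, 12))
  h <- bin_histogram(s, 5)
  expect_equal(h$freq, c(0.25, 0.5, 0.25))
  expect_equal(h$lower, c(0, 5, 10))
  expect_equal(sum(h$freq), 1)
  expect_equal(h$count, h$freq * 4)
  # a boundary value falls in the right-open upper bin
  h2 <- bin_histogram(distance_sequence(c(4, 5)), 5)
  expect_equal(h2$count, c(1, 1))
})

test_that("guinea-pig-like samples are unimodal with the mode near 30 um", {
  s <- gen_distance_sequence(1404, 31.5, 7.8, 1.09, seed = 2)
  h <- bin_histogram(s, 5)
  mode_bin <- h$lower[which.max(h$freq)]
  expect_gte(mode_bin, 20)
  expect_lte(mode_bin, 35)
})

test_that("pig-like samples extend beyond 140 um", {
  s <- gen_distance_sequence(2000, 78.8, 31, 1.4, seed = 3)
  h <- bin_histogram(s, 10)
  expect_gt(max(s$values), 140)
  expect_gt(sum(h$freq[h$lower >= 140]), 0)
})

test_that("rank-sum comparisons behave on identical and shifted samples", {
  a <- distance_sequence(c(21, 25, 28, 30, 31, 33, 36, 40))
  expect_equal(compare_groups(a, a), 1)
  # location tests are invariant to a common offset
  set.seed(5)
  x <- rnorm(30, 30, 5)
  y <- rnorm(30, 33, 5)
  p1 <- compare_groups(x, y)
  p2 <- compare_groups(x + 100, y + 100)
  expect_identical(p1, p2)
})

test_that("exact and normal-approximation rank-sum branches agree", {
  set.seed(9)
  x <- rnorm(20, 30, 5)
  y <- rnorm(20, 32, 5)
  p_exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
  p_norm <- stats::wilcox.test(x, y, exact = FALSE,
                               correct = FALSE)$p.value
  expect_lt(abs(p_exact - p_norm), 0.005)
  expect_equal(compare_groups(x, y), p_exact)
})

test_that("rank-sum test holds its nominal size", {
  set.seed(7)
  rej <- mean(vapply(1:400, function(i) {
    a <- gen_distance_sequence(100, 30, 7, 1, seed = 2 * i)
    b <- gen_distance_sequence(100, 30, 7, 1, seed = 2 * i + 1)
    compare_groups(a, b) < 0.05
  }, NA))
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.08)
})

test_that("matched synthetic blocks reproduce non-significant contrasts", {
  # blocks with near-identical medians (30.9 vs 30.4) and matched spread
  a <- gen_distance_sequence(1404, 31.5, 7.8, 1.09, seed = 8)
  b <- gen_distance_sequence(1876, 31.1, 8.0, 1.09, seed = 9)
  expect_gt(compare_groups(a, b), 0.05)
})

test_that("Kruskal-Wallis detects separated groups and delegates for 2", {
  set.seed(10)
  seqs <- lapply(c(25, 30, 35), function(m) {
    gen_distance_sequence(500, m, 7, 1, seed = round(m))
  })
  expect_lt(kruskal_wallis_groups(seqs), 1e-4)
  two <- seqs[1:2]
  expect_equal(kruskal_wallis_groups(two),
               compare_groups(two[[1]], two[[2]]))
  null_ps <- vapply(1:60, function(i) {
    kruskal_wallis_groups(lapply(1:3, function(j) {
      gen_distance_sequence(100, 30, 7, 1, seed = 100 * i + j)
    }))
  }, 0)
  expect_gte(mean(null_ps < 0.05), 0.0)
  expect_lte(mean(null_ps < 0.05), 0.12)
})

test_that("sequential groups find a known shift and keep traverse order", {
  set.seed(14)
  x <- c(rnorm(100, 30, 4), rnorm(100, 30, 4), rnorm(100, 40, 4))
  s <- distance_sequence(x)
  scan <- sequential_groups(s, 100)
  expect_equal(nrow(scan$groups), 3)
  expect_lt(scan$p_values[2], 0.001)
  expect_gt(scan$p_values[1], 0.05)
  # weighted group means reconstruct the grand mean of the used values
  used <- x[1:300]
  expect_equal(sum(scan$groups$mean * scan$groups$n) / 300, mean(used))
  expect_error(sequential_groups(distance_sequence(rnorm(150, 30, 3) + 30),
                                 100), "at least 200")
})

test_that("the trailing partial group is dropped and reported", {
  s <- distance_sequence(runif(257, 20, 40))
  scan <- sequential_groups(s, 100)
  expect_equal(nrow(scan$groups), 2)
  expect_equal(scan$n_dropped, 57)
  expect_equal(length(scan$p_values), 1)
})

test_that("auto method uses the t-test only for normal-looking groups", {
  set.seed(12)
  x <- c(rnorm(100, 30, 4), rnorm(100, 31, 4))
  scan <- sequential_groups(distance_sequence(abs(x)), 100,
                            method = "auto")
  expect_true(all(scan$tests %in% c("t_test", "mann_whitney")))
  skewed <- gen_distance_sequence(200, 30, 10, 1.8, seed = 13)
  scan2 <- sequential_groups(skewed, 100, method = "t_test")
  expect_equal(scan2$tests, "t_test")
})

test_that("constant-mean scans reject at roughly the nominal rate", {
  rej <- unlist(lapply(1:30, function(i) {
    s <- gen_distance_sequence(1000, 30, 6, 0.8, seed = 500 + i)
    sequential_groups(s, 100)$p_values < 0.05
  }))
  expect_lt(mean(rej), 0.1)
})
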