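test_that("Poisson generator hits the requested mean count", {
  w <- pp_window(0, 1000, 0, 1000)
  # guinea-pig-like orthogonal density, 1 mm^2 of cortex
  counts <- vapply(1:40, function(s) npoints(gen_poisson(1283, w, seed = s)),
                   0L)
  expect_lt(abs(mean(counts) - 1283) / sqrt(1283 / 40), 4)
  expect_equal(npoints(gen_poisson(0, w, seed = 1)), 0)
  expect_error(gen_poisson(-5, w), "non-negative")
  expect_error(gen_poisson(NA, w), "non-negative")
})

test_that("Poisson patterns are unbiased under the Clark-Evans ratio", {
  w <- pp_window(0, 2000, 0, 2000)
  rs <- vapply(1:60, function(s) {
    clark_evans(gen_poisson(125, w, seed = s))$r_ratio
  }, 0)
  expect_lt(abs(mean(rs) - 1), 0.02)
})

test_that("hexagonal lattice is exact at zero jitter", {
  # six equidistant neighbours at 26.67 um
  spacing <- 26.67
  w <- hex_exact_window(spacing, 40, 40)
  p <- gen_hex_lattice(spacing, w)
  expect_equal(npoints(p), 1600)
  # realized density equals the lattice closed form 2/(sqrt(3) d^2)
  expect_equal(pattern_intensity(p, "um"), 2 / (sqrt(3) * spacing^2),
               tolerance = 1e-12)
  # every interior point has >= 6 neighbours at the spacing, to 1e-9
  interior <- boundary_distance(p) >= 1.1 * spacing
  expect_gt(sum(interior), 100)
  xi <- p$x[interior]; yi <- p$y[interior]
  n_at_spacing <- vapply(seq_along(xi), function(i) {
    d <- sqrt((xi[i] - p$x)^2 + (yi[i] - p$y)^2)
    sum(abs(d - spacing) <= 1e-9 * spacing)
  }, 0L)
  expect_true(all(n_at_spacing >= 6))
  expect_equal(min(nn_distances(p)), spacing, tolerance = 1e-12)
  expect_warning(gen_hex_lattice(500, pp_window(0, 100, 0, 100)), "empty")
})

test_that("jittered lattice stays inside the window and perturbs spacing", {
  w <- hex_exact_window(30, 20, 20)
  p <- gen_hex_lattice(30, w, jitter_sd = 2, seed = 5)
  expect_true(all(p$x >= w$x_min & p$x <= w$x_max))
  expect_true(all(p$y >= w$y_min & p$y <= w$y_max))
  expect_gt(stats::sd(nn_distances(p)), 0)
})

test_that("Matern II respects the hard core and its closed-form intensity", {
  w <- pp_window(0, 2000, 0, 2000)
  p <- gen_hardcore(800, 20, w, seed = 2)
  expect_gte(brute_min_pair_dist(p$x, p$y), 20)
  # closed form: retained = (1 - exp(-lambda_p pi h^2)) / (pi h^2)
  lam_p <- 800e-6
  h <- 20
  expected <- (1 - exp(-lam_p * pi * h^2)) / (pi * h^2)
  realized <- vapply(1:30, function(s) {
    pattern_intensity(gen_hardcore(800, 20, w, seed = s), "um")
  }, 0)
  expect_lt(abs(mean(realized) - expected) / expected, 0.03)
  # vanishing hard core recovers the parent intensity
  realized0 <- vapply(1:30, function(s) {
    pattern_intensity(gen_hardcore(800, 0.5, w, seed = s), "um")
  }, 0)
  expect_lt(abs(mean(realized0) - lam_p) / lam_p, 0.03)
  expect_error(gen_hardcore(5e5, 50, w), "packing bound")
})

test_that("banded morphology puts most nearest neighbours at 20-45 um", {
  w <- pp_window(0, 1500, 0, 1500)
  p <- gen_banded(60, 25, window = w, seed = 3)
  nnd <- nn_distances(p)
  expect_gt(mean(nnd >= 20 & nnd <= 45), 0.8)
  expect_warning(gen_banded(20, 25, window = w, seed = 1), "morphology")
})

test_that("a single straight band is collinear at exact spacing", {
  w <- pp_window(0, 50, 0, 500)
  p <- gen_banded(60, 25, wobble = 0, window = w, seed = 4, jitter_sd = 0)
  expect_equal(length(unique(p$x)), 1)
  expect_equal(diff(sort(p$y)), rep(25, npoints(p) - 1))
})

test_that("gradient thinning matches the closed-form half-window ratio", {
  # linear intensity 1 + (r-1)t integrates to a right/left count ratio
  # of (3r + 1) / (r + 3)
  r <- 3
  w <- pp_window(0, 2000, 0, 2000)
  mid <- 1000
  counts <- vapply(1:60, function(s) {
    p <- gen_gradient_poisson(150, r, w, axis = "x", seed = s)
    c(sum(p$x < mid), sum(p$x >= mid))
  }, c(0, 0))
  ratio <- sum(counts[2, ]) / sum(counts[1, ])
  expect_equal(ratio, (3 * r + 1) / (r + 3), tolerance = 0.05)
  expect_error(gen_gradient_poisson(150, 0.5, w), ">= 1")
})

test_that("unit gradient ratio reduces to the homogeneous generator", {
  w <- pp_window(0, 1000, 0, 1000)
  g <- gen_gradient_poisson(300, 1, w, axis = "x", seed = 9)
  h <- gen_poisson(300, w, seed = 9)
  expect_equal(g$x, h$x)
  expect_equal(g$y, h$y)
})

test_that("generators are bit-reproducible and leave the caller RNG alone", {
  w <- pp_window(0, 1000, 0, 1000)
  gens <- list(
    function(s) gen_poisson(400, w, seed = s),
    function(s) gen_hex_lattice(30, w, jitter_sd = 2, seed = s),
    function(s) gen_hardcore(600, 15, w, seed = s),
    function(s) gen_banded(60, 25, window = w, seed = s),
    function(s) gen_gradient_poisson(200, 2, w, axis = "y", seed = s))
  for (g in gens) {
    a <- g(42)
    b <- g(42)
    expect_identical(a$x, b$x)
    expect_identical(a$y, b$y)
    expect_true(all(a$x >= w$x_min & a$x <= w$x_max &
                    a$y >= w$y_min & a$y <= w$y_max))
  }
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(gen_poisson(400, w, seed = 7))
  expect_identical(runif(1), before)
})

test_that("distinct seeds give statistically indistinguishable ensembles", {
  w <- pp_window(0, 1500, 0, 1500)
  p1 <- gen_poisson(500, w, seed = 101)
  p2 <- gen_poisson(500, w, seed = 202)
  ks <- suppressWarnings(
    stats::ks.test(nn_distances(p1), nn_distances(p2)))
  expect_gt(ks$p.value, 0.01)
  b1 <- gen_banded(60, 25, window = w, seed = 301)
  b2 <- gen_banded(60, 25, window = w, seed = 401)
  ks2 <- suppressWarnings(
    stats::ks.test(nn_distances(b1), nn_distances(b2)))
  expect_gt(ks2$p.value, 0.01)
})
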