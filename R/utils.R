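# internal helpers

# Run code under a locally scoped seed; NULL leaves the caller's RNG stream
# untouched and consumes from it.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), force(code))
}

# default radius grid: 100 points from 0 to min(window sides)/4
default_radii <- function(window, n = 100L) {
  seq(0, window_min_side(window) / 4, length.out = n)
}

# squared pairwise distances between chunk idx and all points (matrix)
chunk_dist2 <- function(p, idx) {
  dx <- outer(p$x[idx], p$x, "-")
  dy <- outer(p$y[idx], p$y, "-")
  dx * dx + dy * dy
}
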