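# Independent brute-force oracles, deliberately written as plain double
# loops over the raw coordinates so they share no code with the
# estimators they check.

brute_K_none <- function(x, y, area, radii) {
  n <- length(x)
  vapply(radii, function(r) {
    cnt <- 0
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) {
          d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
          if (d <= r) cnt <- cnt + 1
        }
      }
    }
    area / n^2 * cnt
  }, 0)
}

brute_G_none <- function(x, y, radii) {
  n <- length(x)
  nnd <- vapply(seq_len(n), function(i) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        if (d < best) best <- d
      }
    }
    best
  }, 0)
  vapply(radii, function(r) mean(nnd <= r), 0)
}

brute_min_pair_dist <- function(x, y) {
  n <- length(x)
  best <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d < best) best <- d
    }
  }
  best
}

# Clark-Evans ratio for a perfect hexagonal packing: 2 * sqrt(2) * 3^(-1/4)
R_HEX <- 2 * sqrt(2) * 3^(-1 / 4)

# window sized to hold an exact integer number of hex cells so that the
# realized intensity equals 2 / (sqrt(3) spacing^2) exactly
hex_exact_window <- function(spacing, n_cols, n_rows) {
  pp_window(0, n_cols * spacing, 0, n_rows * spacing * sqrt(3) / 2)
}
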