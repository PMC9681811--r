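#' Synthetic bundle-map generators
#'
#' Seeded generators for the point-pattern morphologies the downstream
#' statistics are designed to distinguish: complete spatial randomness,
#' a hexagonal lattice (the idealized equidistant arrangement), a Matern
#' type II hard-core process (regular but not lattice-like), curving
#' quasi-parallel strings of bundles (the arrangement actually observed in
#' tangential cortical sections), and an inhomogeneous Poisson process with
#' a linear density gradient (the smooth macro-inhomogeneity seen across
#' whole sections).
#'
#' All coordinates are in micrometres; intensities are supplied in bundles
#' per square millimetre, the unit used for reported densities. Every
#' generator is bit-reproducible for a fixed integer `seed` (the seed is
#' applied locally and the caller's RNG state is untouched).
#'
#' @name generators
NULL

MM2_TO_UM2 <- 1e-6  # bundles/mm^2 -> bundles/um^2

#' Homogeneous Poisson bundle map
#'
#' The "benchmark" completely random process: the point count is
#' Poisson(intensity x area) and coordinates are i.i.d. uniform in the
#' window.
#'
#' @param intensity Mean density in bundles per mm^2; must be positive
#'   (zero is allowed and yields an empty pattern).
#' @param window A [pp_window()].
#' @param seed Optional integer seed for reproducibility.
#' @param label Pattern label.
#' @return A [point_pattern()].
#' @examples
#' p <- gen_poisson(643, pp_window(0, 1000, 0, 1000), seed = 1)
#' @export
gen_poisson <- function(intensity, window, seed = NULL, label = "poisson") {
  stopifnot(inherits(window, "pp_window"))
  if (!is.finite(intensity) || intensity < 0) {
    stop("intensity must be a non-negative finite density (bundles/mm^2)",
         call. = FALSE)
  }
  lam_um <- intensity * MM2_TO_UM2
  with_local_seed(seed, {
    n <- stats::rpois(1, lam_um * window_area(window))
    x <- stats::runif(n, window$x_min, window$x_max)
    y <- stats::runif(n, window$y_min, window$y_max)
    point_pattern(x, y, window, label)
  })
}

#' Jittered hexagonal (triangular) lattice
#'
#' Points of a triangular lattice clipped to the window, optionally
#' perturbed by isotropic Gaussian jitter. With zero jitter every interior
#' point is equidistant from its six nearest neighbours at exactly
#' `spacing`, and the realized density is 2 / (sqrt(3) * spacing^2).
#' Rows are separated by spacing * sqrt(3) / 2 and offset by half a
#' spacing; the lattice is inset by half a cell so that a window whose
#' sides are exact multiples of the column and row pitches holds an exact
#' integer number of points.
#'
#' @param spacing Nearest-neighbour spacing in micrometres.
#' @param window A [pp_window()].
#' @param jitter_sd Gaussian jitter SD in micrometres (default 0).
#' @param seed Optional integer seed (only used when `jitter_sd > 0`).
#' @param label Pattern label.
#' @return A [point_pattern()].
#' @export
gen_hex_lattice <- function(spacing, window, jitter_sd = 0, seed = NULL,
                            label = "hex_lattice") {
  stopifnot(inherits(window, "pp_window"))
  if (!is.finite(spacing) || spacing <= 0) {
    stop("spacing must be positive", call. = FALSE)
  }
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  dy <- spacing * sqrt(3) / 2
  wx <- window$x_max - window$x_min
  wy <- window$y_max - window$y_min
  rows <- seq_len(max(0L, floor(wy / dy + 1)))
  xs <- ys <- numeric(0)
  for (j in rows) {
    yj <- window$y_min + dy / 2 + (j - 1) * dy
    if (yj >= window$y_max) next
    off <- if (j %% 2 == 1) spacing / 4 else 3 * spacing / 4
    xr <- seq(window$x_min + off, window$x_max - 1e-9, by = spacing)
    xs <- c(xs, xr)
    ys <- c(ys, rep(yj, length(xr)))
  }
  if (length(xs) == 0) {
    warning("spacing larger than window extent: empty pattern")
    return(point_pattern(numeric(0), numeric(0), window, label))
  }
  if (jitter_sd > 0) {
    pat <- with_local_seed(seed, {
      x <- xs + stats::rnorm(length(xs), 0, jitter_sd)
      y <- ys + stats::rnorm(length(ys), 0, jitter_sd)
      keep <- x >= window$x_min & x <= window$x_max &
              y >= window$y_min & y <= window$y_max
      point_pattern(x[keep], y[keep], window, label)
    })
    return(pat)
  }
  point_pattern(xs, ys, window, label)
}

#' Matern type II hard-core bundle map
#'
#' Proposals are drawn from a homogeneous Poisson parent of the given
#' intensity and carry i.i.d. uniform marks; a proposal is deleted when any
#' other proposal with a smaller mark lies within `min_dist`. No two
#' retained points are closer than `min_dist`. The retained intensity has
#' the closed form (1 - exp(-lambda_p * pi * h^2)) / (pi * h^2) for parent
#' intensity lambda_p and hard-core distance h.
#'
#' @param intensity Parent Poisson intensity in bundles per mm^2.
#' @param min_dist Hard-core (minimum inter-point) distance in micrometres.
#' @param window A [pp_window()].
#' @param seed Optional integer seed.
#' @param label Pattern label.
#' @return A [point_pattern()].
#' @export
gen_hardcore <- function(intensity, min_dist, window, seed = NULL,
                         label = "hardcore") {
  stopifnot(inherits(window, "pp_window"))
  if (!is.finite(intensity) || intensity <= 0) {
    stop("parent intensity must be positive", call. = FALSE)
  }
  if (!is.finite(min_dist) || min_dist <= 0) {
    stop("min_dist must be positive", call. = FALSE)
  }
  # area fraction of disks of diameter h at the parent intensity; the
  # densest packing with minimum spacing h (hexagonal) has fraction
  # pi / (2 sqrt(3)) ~ 0.9069
  frac <- intensity * MM2_TO_UM2 * pi * min_dist^2 / 4
  if (frac >= pi / (2 * sqrt(3))) {
    stop(sprintf(paste0(
      "infeasible parameters: disk area fraction %.3f exceeds the ",
      "hexagonal packing bound pi/(2*sqrt(3)) = %.4f"),
      frac, pi / (2 * sqrt(3))), call. = FALSE)
  }
  with_local_seed(seed, {
    parent <- gen_poisson(intensity, window, seed = NULL, label = label)
    n <- npoints(parent)
    if (n == 0) return(parent)
    marks <- stats::runif(n)
    keep <- rep(TRUE, n)
    block <- 512L
    h2 <- min_dist^2
    for (start in seq(1L, n, by = block)) {
      idx <- start:min(start + block - 1L, n)
      dx <- outer(parent$x[idx], parent$x, "-")
      dy <- outer(parent$y[idx], parent$y, "-")
      close <- (dx * dx + dy * dy) < h2
      close[cbind(seq_along(idx), idx)] <- FALSE
      earlier <- outer(marks[idx], marks, ">")
      keep[idx] <- rowSums(close & earlier) == 0
    }
    point_pattern(parent$x[keep], parent$y[keep], window, label)
  })
}

#' Banded string arrangement of bundles
#'
#' Emulates the observed morphology of bundle maps: thin curving,
#' quasi-parallel strings of closely adjacent bundles separated by broader
#' empty bands. Strings run along the y axis with centre-to-centre lateral
#' spacing `band_spacing`; along each string, points are laid down every
#' `along_spacing` micrometres. Each string is displaced laterally by a
#' sinusoid of amplitude `wobble` with a random phase (period
#' `wobble_period`), and every point receives a small isotropic Gaussian
#' jitter so that strings are irregular rather than ruler-straight.
#' Optionally a string can bifurcate: with probability `branch_prob` per
#' micrometre of string length a branch diverges to the midline of the
#' neighbouring gap and then runs parallel.
#'
#' @param band_spacing String-to-string spacing in micrometres.
#' @param along_spacing Along-string point spacing in micrometres. The
#'   observed morphology has `band_spacing > along_spacing`; other
#'   orderings are accepted with a warning.
#' @param wobble Sinusoidal perturbation amplitude in micrometres
#'   (default 18, calibrated so the default morphology reproduces the
#'   regularity signatures of traced bundle maps).
#' @param window A [pp_window()].
#' @param seed Optional integer seed.
#' @param wobble_period Sinusoid period in micrometres (default 1000).
#' @param jitter_sd Per-point isotropic jitter SD in micrometres
#'   (default 1.5, the scale of digitization noise when plotting bundle
#'   centres).
#' @param branch_prob Branching probability per micrometre of string
#'   (default 0, i.e. no branching).
#' @param label Pattern label.
#' @return A [point_pattern()].
#' @export
gen_banded <- function(band_spacing, along_spacing, wobble = 18, window,
                       seed = NULL, wobble_period = 1000,
                       jitter_sd = 1.5, branch_prob = 0,
                       label = "banded") {
  stopifnot(inherits(window, "pp_window"))
  if (band_spacing <= 0 || along_spacing <= 0) {
    stop("band_spacing and along_spacing must be positive", call. = FALSE)
  }
  if (wobble < 0 || wobble_period <= 0 || jitter_sd < 0 || branch_prob < 0) {
    stop("wobble, wobble_period, jitter_sd and branch_prob must be",
         " non-negative (period positive)", call. = FALSE)
  }
  if (band_spacing <= along_spacing) {
    warning("band_spacing <= along_spacing does not reproduce the banded",
            " morphology (strings closer than their internal spacing)")
  }
  with_local_seed(seed, {
    bases <- seq(window$x_min - wobble + band_spacing / 2,
                 window$x_max + wobble, by = band_spacing)
    xs <- ys <- numeric(0)
    lay_string <- function(base, y0, phase, diverge_to = NA) {
      yy <- seq(y0, window$y_max, by = along_spacing)
      if (length(yy) == 0) return(NULL)
      xx <- base + wobble * sin(2 * pi * yy / wobble_period + phase)
      if (!is.na(diverge_to)) {
        # branch: drift from the parent string to the gap midline over
        # roughly two band spacings, then run parallel
        drift <- pmin(1, (yy - y0) / (2 * band_spacing))
        xx <- xx + drift * (diverge_to - base)
      }
      list(x = xx, y = yy)
    }
    for (base in bases) {
      phase <- stats::runif(1, 0, 2 * pi)
      y0 <- window$y_min + stats::runif(1, 0, along_spacing)
      s <- lay_string(base, y0, phase)
      if (is.null(s)) next
      xs <- c(xs, s$x); ys <- c(ys, s$y)
      if (branch_prob > 0) {
        len <- window$y_max - y0
        n_branch <- stats::rpois(1, branch_prob * len)
        if (n_branch > 0) {
          by0 <- stats::runif(n_branch, y0, window$y_max)
          for (b in by0) {
            side <- sample(c(-1, 1), 1)
            sb <- lay_string(base, b, phase,
                             diverge_to = base + side * band_spacing / 2)
            if (!is.null(sb)) { xs <- c(xs, sb$x); ys <- c(ys, sb$y) }
          }
        }
      }
    }
    if (jitter_sd > 0) {
      xs <- xs + stats::rnorm(length(xs), 0, jitter_sd)
      ys <- ys + stats::rnorm(length(ys), 0, jitter_sd)
    }
    keep <- xs >= window$x_min & xs <= window$x_max &
            ys >= window$y_min & ys <= window$y_max
    point_pattern(xs[keep], ys[keep], window, label)
  })
}

#' Inhomogeneous Poisson map with a linear density gradient
#'
#' Intensity varies linearly along the chosen axis from `base_intensity`
#' at the low edge of the window to `base_intensity * gradient_ratio` at
#' the high edge. Generated by independent thinning of a homogeneous
#' parent at the maximum intensity, so the result is an exact
#' inhomogeneous Poisson realization.
#'
#' @param base_intensity Intensity at the low edge, bundles per mm^2.
#' @param gradient_ratio Ratio of high-edge to low-edge intensity
#'   (must be >= 1; 1 recovers the homogeneous process).
#' @param window A [pp_window()].
#' @param axis `"x"` or `"y"`: the axis along which density increases.
#' @param seed Optional integer seed.
#' @param label Pattern label.
#' @return A [point_pattern()].
#' @export
gen_gradient_poisson <- function(base_intensity, gradient_ratio, window,
                                 axis = c("x", "y"), seed = NULL,
                                 label = "gradient_poisson") {
  axis <- match.arg(axis)
  stopifnot(inherits(window, "pp_window"))
  if (!is.finite(base_intensity) || base_intensity <= 0) {
    stop("base_intensity must be positive", call. = FALSE)
  }
  if (!is.finite(gradient_ratio) || gradient_ratio < 1) {
    stop("gradient_ratio must be >= 1", call. = FALSE)
  }
  with_local_seed(seed, {
    parent <- gen_poisson(base_intensity * gradient_ratio, window,
                          seed = NULL, label = label)
    if (npoints(parent) == 0) return(parent)
    lo <- if (axis == "x") window$x_min else window$y_min
    hi <- if (axis == "x") window$x_max else window$y_max
    t <- ((if (axis == "x") parent$x else parent$y) - lo) / (hi - lo)
    p_keep <- (1 + (gradient_ratio - 1) * t) / gradient_ratio
    keep <- stats::runif(npoints(parent)) < p_keep
    point_pattern(parent$x[keep], parent$y[keep], window, label)
  })
}
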