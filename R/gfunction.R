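#' Nearest-neighbour distance distribution function G
#'
#' G(r) is the proportion of nearest-neighbour distances below r. Under
#' complete spatial randomness G(r) = 1 - exp(-lambda pi r^2); the curve
#' carries this benchmark and the difference `diff = g_hat - poisson_g`,
#' whose negative values at small r indicate that nearest neighbours sit
#' further away than a random arrangement would place them (regularity).
#'
#' Corrections: `"border"` (default) is the reduced-sample estimator,
#' counting at radius r only points at least r from the boundary;
#' `"none"` is the raw empirical CDF of all nearest-neighbour distances.
#'
#' @param pattern A [point_pattern()] with at least 2 points.
#' @param radii Radius grid in micrometres; defaults to 100 values from 0
#'   to a quarter of the shorter window side.
#' @param correction `"border"` or `"none"`.
#' @return An object of class `g_curve` with elements `radii`, `g_hat`,
#'   `poisson_g`, `diff`, `lambda`, `correction`, `n`.
#' @export
estimate_G <- function(pattern, radii = NULL,
                       correction = c("border", "none")) {
  correction <- match.arg(correction)
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  if (n < 2) stop("G function undefined for fewer than 2 points",
                  call. = FALSE)
  w <- pattern$window
  if (is.null(radii)) radii <- default_radii(w)
  radii <- sort(radii)
  if (any(radii < 0)) stop("radii must be non-negative", call. = FALSE)
  lam <- n / window_area(w)
  nnd <- nn_distances(pattern)
  if (correction == "border") {
    bd <- boundary_distance(pattern)
    g_hat <- vapply(radii, function(r) {
      elig <- bd >= r
      m <- sum(elig)
      if (m == 0) return(NA_real_)
      sum(nnd[elig] <= r) / m
    }, 0)
    if (anyNA(g_hat)) {
      for (k in seq_along(g_hat)) {
        if (is.na(g_hat[k])) g_hat[k] <- if (k > 1) g_hat[k - 1] else 0
      }
    }
    # reduced-sample curves need not be monotone; enforce the CDF property
    g_hat <- cummax(g_hat)
  } else {
    sorted <- sort(nnd)
    g_hat <- findInterval(radii, sorted) / n
  }
  poisson_g <- 1 - exp(-lam * pi * radii^2)
  structure(list(radii = radii, g_hat = g_hat, poisson_g = poisson_g,
                 diff = g_hat - poisson_g, lambda = lam,
                 correction = correction, n = n),
            class = "g_curve")
}

#' @export
print.g_curve <- function(x, ...) {
  cat(sprintf("G curve: %d radii up to %g um, correction = %s, n = %d\n",
              length(x$radii), max(x$radii), x$correction, x$n))
  cat(sprintf("max |G - Poisson| = %.4f\n", max(abs(x$diff))))
  invisible(x)
}

#' @export
plot.g_curve <- function(x, what = c("diff", "cdf"), ...) {
  what <- match.arg(what)
  if (what == "diff") {
    plot(x$radii, x$diff, type = "l", xlab = "r (um)",
         ylab = "G(r) - Poisson", ...)
    graphics::abline(h = 0, lty = 2, col = "grey50")
  } else {
    plot(x$radii, x$g_hat, type = "l", xlab = "r (um)", ylab = "G(r)",
         ylim = c(0, 1), ...)
    graphics::lines(x$radii, x$poisson_g, lty = 2, col = "grey50")
  }
  invisible(x)
}
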