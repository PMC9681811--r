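#' Planar point pattern of bundle centres
#'
#' A set of 2-D bundle-centre coordinates (micrometres) together with its
#' rectangular analysis window. The pattern intensity lambda = n / area is
#' the convention used throughout: no fitted or adaptive intensity enters
#' the regularity statistics.
#'
#' @param x,y Numeric coordinate vectors in micrometres.
#' @param window A [pp_window()].
#' @param label Optional free-text label (e.g. section or species id).
#' @return An object of class `point_pattern` with elements `x`, `y`,
#'   `window`, `label`.
#' @examples
#' w <- pp_window(0, 100, 0, 100)
#' p <- point_pattern(c(10, 50, 90), c(20, 50, 80), w)
#' npoints(p)
#' pattern_intensity(p, "mm")
#' @export
point_pattern <- function(x, y, window, label = "") {
  stopifnot(inherits(window, "pp_window"))
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have the same length", call. = FALSE)
  }
  if (length(x) > 0) {
    if (any(!is.finite(x)) || any(!is.finite(y))) {
      stop("coordinates must be finite", call. = FALSE)
    }
    out <- x < window$x_min | x > window$x_max |
           y < window$y_min | y > window$y_max
    if (any(out)) {
      stop(sprintf("%d point(s) lie outside the declared window", sum(out)),
           call. = FALSE)
    }
  }
  structure(list(x = x, y = y, window = window, label = label),
            class = "point_pattern")
}

#' Number of points in a pattern
#' @param p A `point_pattern`.
#' @export
npoints <- function(p) {
  stopifnot(inherits(p, "point_pattern"))
  length(p$x)
}

#' Pattern intensity lambda = n / window area
#'
#' @param p A `point_pattern`.
#' @param units `"um"` for points per square micrometre (the internal unit)
#'   or `"mm"` for bundles per square millimetre (the reporting unit;
#'   a factor of 1e6 larger).
#' @export
pattern_intensity <- function(p, units = c("um", "mm")) {
  units <- match.arg(units)
  lam <- npoints(p) / window_area(p$window)
  if (units == "mm") lam * 1e6 else lam
}

#' Distance from each point to the window boundary
#' @param p A `point_pattern`.
#' @return Numeric vector of boundary distances in micrometres.
#' @export
boundary_distance <- function(p) {
  w <- p$window
  pmin(p$x - w$x_min, w$x_max - p$x, p$y - w$y_min, w$y_max - p$y)
}

#' Nearest-neighbour distance of every point
#'
#' Computed by blocked pairwise evaluation, so memory stays linear in n
#' even for lattice-sized patterns.
#'
#' @param p A `point_pattern` with at least 2 points.
#' @return Numeric vector of nearest-neighbour distances in micrometres.
#' @export
nn_distances <- function(p) {
  n <- npoints(p)
  if (n < 2) stop("nearest-neighbour distances need at least 2 points",
                  call. = FALSE)
  block <- 512L
  out <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    dx <- outer(p$x[idx], p$x, "-")
    dy <- outer(p$y[idx], p$y, "-")
    d2 <- dx * dx + dy * dy
    d2[cbind(seq_along(idx), idx)] <- Inf
    out[idx] <- sqrt(apply(d2, 1, min))
  }
  out
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d points%s\n", npoints(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  print(x$window)
  cat(sprintf("intensity: %.6g per um^2 (%.6g per mm^2)\n",
              pattern_intensity(x, "um"), pattern_intensity(x, "mm")))
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ..., pch = 16, cex = 0.4, asp = 1) {
  w <- x$window
  plot(x$x, x$y, pch = pch, cex = cex, asp = asp,
       xlim = c(w$x_min, w$x_max), ylim = c(w$y_min, w$y_max),
       xlab = "x (um)", ylab = "y (um)", ...)
  graphics::rect(w$x_min, w$y_min, w$x_max, w$y_max, border = "grey40")
  invisible(x)
}
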