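#' Rectangular analysis window
#'
#' The analysis window is the axis-aligned rectangle over which a bundle map
#' was traced. All coordinates are in micrometres. The window defines the
#' reference intensity used by every regularity statistic: lambda is always
#' the number of points divided by the window area.
#'
#' @param x_min,x_max,y_min,y_max Window limits in micrometres.
#' @return An object of class `pp_window`.
#' @examples
#' w <- pp_window(0, 1000, 0, 1000)
#' window_area(w)
#' @export
pp_window <- function(x_min, x_max, y_min, y_max) {
  vals <- c(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max)
  if (any(!is.finite(vals))) {
    stop("window limits must be finite numbers", call. = FALSE)
  }
  if (x_max <= x_min || y_max <= y_min) {
    stop("degenerate window: need x_max > x_min and y_max > y_min",
         call. = FALSE)
  }
  structure(list(x_min = x_min, x_max = x_max,
                 y_min = y_min, y_max = y_max),
            class = "pp_window")
}

#' @rdname pp_window
#' @param w A `pp_window`.
#' @export
window_area <- function(w) {
  stopifnot(inherits(w, "pp_window"))
  (w$x_max - w$x_min) * (w$y_max - w$y_min)
}

#' Shorter side of a window, in micrometres
#' @param w A `pp_window`.
#' @export
window_min_side <- function(w) {
  stopifnot(inherits(w, "pp_window"))
  min(w$x_max - w$x_min, w$y_max - w$y_min)
}

#' @export
print.pp_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] um (area %g um^2)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, window_area(x)))
  invisible(x)
}
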