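#' Write a point pattern to TSV
#'
#' Tab-separated columns `x_um`, `y_um`, one point per row, preceded by a
#' `#window:` comment line carrying the analysis window as JSON. The
#' format round-trips exactly through [read_point_pattern()].
#'
#' @param pattern A [point_pattern()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_point_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  w <- pattern$window
  header <- paste0("#window: ", jsonlite::toJSON(
    list(x_min = w$x_min, x_max = w$x_max,
         y_min = w$y_min, y_max = w$y_max),
    auto_unbox = TRUE, digits = NA))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines("x_um\ty_um", con)
  if (npoints(pattern) > 0) {
    writeLines(paste(format(pattern$x, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     format(pattern$y, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a point pattern from TSV
#'
#' Expects a header line `x_um<TAB>y_um` and one point per row. The
#' analysis window is taken from a `#window:` JSON comment line or from a
#' sidecar file `<path>.json`; if neither exists, the bounding box
#' expanded by 2% is used with a warning. A third coordinate column, if
#' present, is dropped with a warning (analysis is planar). Malformed
#' rows and points outside the declared window are errors.
#'
#' @param path Input file path.
#' @param label Pattern label (defaults to the file name).
#' @return A [point_pattern()].
#' @export
read_point_pattern <- function(path, label = basename(path)) {
  lines <- readLines(path)
  win <- NULL
  wline <- grep("^#window:", lines)
  if (length(wline) > 0) {
    spec <- jsonlite::fromJSON(sub("^#window:\\s*", "", lines[wline[1]]))
    win <- pp_window(spec$x_min, spec$x_max, spec$y_min, spec$y_max)
  } else if (file.exists(paste0(path, ".json"))) {
    spec <- jsonlite::fromJSON(paste0(path, ".json"))
    win <- pp_window(spec$x_min, spec$x_max, spec$y_min, spec$y_max)
  }
  body_idx <- which(!startsWith(lines, "#"))
  if (length(body_idx) == 0) stop("no header line found", call. = FALSE)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "x_um" || header[2] != "y_um") {
    stop("expected header 'x_um<TAB>y_um'", call. = FALSE)
  }
  if (length(header) > 2) {
    warning("extra coordinate column(s) dropped: analysis is planar")
  }
  data_idx <- body_idx[-1]
  n <- length(data_idx)
  x <- y <- numeric(n)
  for (i in seq_len(n)) {
    fields <- strsplit(lines[data_idx[i]], "\t", fixed = TRUE)[[1]]
    xv <- suppressWarnings(as.numeric(fields[1]))
    yv <- suppressWarnings(as.numeric(fields[2]))
    if (length(fields) < 2 || is.na(xv) || is.na(yv)) {
      stop(sprintf("malformed row at line %d of %s", data_idx[i], path),
           call. = FALSE)
    }
    x[i] <- xv; y[i] <- yv
  }
  dup <- sum(duplicated(cbind(x, y)))
  if (dup > 0) {
    message(sprintf("%d duplicate coordinate(s) in %s", dup, path))
  }
  if (is.null(win)) {
    warning("no window declared; using bounding box + 2% margin")
    mx <- 0.02 * max(diff(range(x)), 1e-6)
    my <- 0.02 * max(diff(range(y)), 1e-6)
    win <- pp_window(min(x) - mx, max(x) + mx, min(y) - my, max(y) + my)
  }
  point_pattern(x, y, win, label)
}

#' Write a distance sequence to single-column TSV
#'
#' @param seq A [distance_sequence()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "distance_sequence"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("distance_um", con)
  writeLines(format(seq$values, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Read an ordered distance sequence from TSV
#'
#' Expects a `distance_um` column; a `block` column, if present, splits
#' the file into one sequence per block (order within block preserved).
#'
#' @param path Input file path.
#' @return A [distance_sequence()], or a named list of them when a
#'   `block` column is present.
#' @export
read_distance_sequence <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!"distance_um" %in% names(df)) {
    stop("expected a 'distance_um' column", call. = FALSE)
  }
  if ("block" %in% names(df)) {
    sp <- split(df$distance_um, factor(df$block, unique(df$block)))
    return(lapply(names(sp), function(b) {
      distance_sequence(sp[[b]], block = b)
    }) |> stats::setNames(names(sp)))
  }
  distance_sequence(df$distance_um)
}
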