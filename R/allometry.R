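#' Packaged cross-species measurement table
#'
#' Visual and body measurements for the ten species used in the
#' cross-species analysis: eye axial diameter (mm), total retinal
#' ganglion cells (millions), visual acuity (cycles/degree), body mass
#' (kg), left V-1 surface area (mm^2), total V-1 neurons (millions),
#' median inter-bundle distance (um), and bundle densities measured in
#' orthogonal and (where available) tangential sections (bundles/mm^2).
#' Missing entries are `NA`. The `printed_*` columns carry the derived
#' values as originally published; they are not used by the derivation
#' functions, which recompute everything from the measurement columns
#' (note the published hedgehog total, 8,665, differs from the 591 x 15 =
#' 8,865 its own density and area imply, and the published primate
#' neurons-per-column values are not consistent with the cylinder model
#' and the tabulated V-1 neuron totals).
#'
#' @return A data frame with one row per species.
#' @export
load_species_table <- function() {
  path <- system.file("extdata", "species_table.tsv", package = "minicol",
                      mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}

#' Estimated total bundle count in left V-1
#'
#' Bundle density times V-1 area, rounded to the nearest integer.
#' Vectorized; missing inputs give `NA` (a missing-value result, not
#' zero).
#'
#' @param bundle_density Bundles per mm^2.
#' @param v1_area V-1 surface area in mm^2.
#' @return Estimated count(s).
#' @examples
#' total_bundles(1773, 78)    # ferret: 138294
#' total_bundles(2318, 1269)  # macaque: 2941542
#' @export
total_bundles <- function(bundle_density, v1_area) {
  ok <- !is.na(bundle_density) & !is.na(v1_area)
  if (any(ok & (bundle_density <= 0 | v1_area <= 0))) {
    stop("bundle density and area must be positive", call. = FALSE)
  }
  round(bundle_density * v1_area)
}

#' Derived total-bundle estimates for a species table
#'
#' For species with both orthogonal and tangential densities the two
#' products bracket the estimate; `range_policy` selects which value
#' represents the species in downstream fits. `"high"` coincides with
#' the orthogonal-section density for every species in the packaged
#' table (tangential densities, where measured, are the lower of the
#' two), so it is also the "orthogonal-only" reading.
#'
#' @param table A data frame as returned by [load_species_table()].
#' @param range_policy `"midpoint"` (default), `"low"` or `"high"`.
#' @return A data frame with `species`, `total_low`, `total_high`,
#'   `total` (the policy value).
#' @export
derive_total_bundles <- function(table,
                                 range_policy = c("midpoint", "low",
                                                  "high")) {
  range_policy <- match.arg(range_policy)
  d1 <- table$bundle_density_orth_mm2
  d2 <- table$bundle_density_tang_mm2
  lo <- ifelse(is.na(d2), d1, pmin(d1, d2))
  hi <- ifelse(is.na(d2), d1, pmax(d1, d2))
  total_low <- total_bundles(lo, table$v1_area_mm2)
  total_high <- total_bundles(hi, table$v1_area_mm2)
  total <- switch(range_policy,
                  midpoint = round((total_low + total_high) / 2),
                  low = total_low,
                  high = total_high)
  data.frame(species = table$species, total_low = total_low,
             total_high = total_high, total = total)
}

#' Neurons per minicolumn under the cylinder model
#'
#' Treats each myelin bundle as a cylinder whose diameter is the median
#' inter-bundle distance and fills it at the areal neuron density of V-1:
#' (total neurons / area) * pi * (d/2)^2, with the cylinder
#' cross-section converted from um^2 to mm^2, rounded to the nearest
#' integer. Vectorized; missing inputs give `NA`.
#'
#' @param v1_neurons_millions Total V-1 neurons in millions.
#' @param v1_area_mm2 V-1 surface area in mm^2.
#' @param interbundle_distance_um Median inter-bundle distance in um.
#' @return Estimated neuron count(s) per column.
#' @examples
#' neurons_per_column(0.71, 7.1, 27)    # rat: 57
#' neurons_per_column(1.35, 13.5, 31.5) # guinea pig: 78
#' @export
neurons_per_column <- function(v1_neurons_millions, v1_area_mm2,
                               interbundle_distance_um) {
  ok <- !is.na(v1_neurons_millions) & !is.na(v1_area_mm2) &
        !is.na(interbundle_distance_um)
  if (any(ok & (v1_neurons_millions <= 0 | v1_area_mm2 <= 0 |
                interbundle_distance_um <= 0))) {
    stop("all inputs must be positive", call. = FALSE)
  }
  areal <- v1_neurons_millions * 1e6 / v1_area_mm2          # per mm^2
  cyl_mm2 <- pi * (interbundle_distance_um / 2)^2 * 1e-6    # um^2 -> mm^2
  round(areal * cyl_mm2)
}

#' Minicolumns per orientation pinwheel
#'
#' Total bundle count divided by the number of orientation pinwheels in
#' V-1, rounded to the nearest integer. Dividing further by the number of
#' orientation columns per pinwheel (conventionally 15) gives minicolumns
#' per orientation column.
#'
#' @param total_bundles Estimated total bundles in V-1 (> 0).
#' @param n_pinwheels Number of pinwheels (> 0).
#' @param per_orientation_column Also divide by
#'   `n_orientation_columns` (default FALSE).
#' @param n_orientation_columns Orientation columns per pinwheel
#'   (default 15).
#' @return Rounded quotient.
#' @examples
#' per_pinwheel(138294, 429)     # ferret: 322
#' per_pinwheel(2941542, 10152)  # macaque: 290
#' @export
per_pinwheel <- function(total_bundles, n_pinwheels,
                         per_orientation_column = FALSE,
                         n_orientation_columns = 15) {
  if (any(n_pinwheels <= 0)) stop("n_pinwheels must be positive",
                                  call. = FALSE)
  if (any(total_bundles <= 0)) stop("total_bundles must be positive",
                                    call. = FALSE)
  q <- total_bundles / n_pinwheels
  if (per_orientation_column) q <- q / n_orientation_columns
  round(q)
}

#' Power-law regression between species-level quantities
#'
#' Fits y = a * x^b across species. With `fit_space = "log"` (default)
#' the fit is ordinary least squares of log10(y) on log10(x) and R^2 is
#' the squared correlation of the logs. With `fit_space = "linear"` the
#' power curve is fitted by nonlinear least squares on the original
#' scale (started from the log-log solution) and R^2 is computed from
#' linear-scale residuals - the convention of common graphing software,
#' which weights large-valued species heavily. Pairs with a missing
#' value are excluded from the fit and listed; non-positive values are
#' an error (the log is undefined).
#'
#' @param x,y Positive species-level values (may contain `NA`).
#' @param names Optional species names, used for the exclusion list.
#' @param fit_space `"log"` or `"linear"`.
#' @return A list of class `powerlaw_fit` with `exponent`, `intercept`
#'   (log10 of the prefactor a), `r_squared`, `n_points`, `excluded`,
#'   `fit_space`.
#' @examples
#' f <- powerlaw_fit(c(1, 2, 4, 8), c(2, 8, 32, 128))  # y = 2 x^2
#' f$exponent
#' @export
powerlaw_fit <- function(x, y, names = NULL,
                         fit_space = c("log", "linear")) {
  fit_space <- match.arg(fit_space)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (is.null(names)) names <- paste0("obs", seq_along(x))
  keep <- !is.na(x) & !is.na(y)
  if (any(keep & (x <= 0 | y <= 0))) {
    stop("power-law fit needs strictly positive values", call. = FALSE)
  }
  if (sum(keep) < 3) {
    stop("power-law fit needs at least 3 complete pairs", call. = FALSE)
  }
  xs <- x[keep]; ys <- y[keep]
  lf <- stats::lm(log10(ys) ~ log10(xs))
  if (fit_space == "log") {
    exponent <- unname(stats::coef(lf)[2])
    intercept <- unname(stats::coef(lf)[1])
    r2 <- stats::cor(log10(xs), log10(ys))^2
  } else {
    start <- list(a = 10^unname(stats::coef(lf)[1]),
                  b = unname(stats::coef(lf)[2]))
    nf <- stats::nls(ys ~ a * xs^b, start = start,
                     control = stats::nls.control(maxiter = 500,
                                                  scaleOffset = 1))
    exponent <- unname(stats::coef(nf)["b"])
    intercept <- log10(unname(stats::coef(nf)["a"]))
    r2 <- 1 - sum(stats::residuals(nf)^2) / sum((ys - mean(ys))^2)
  }
  structure(list(exponent = exponent, intercept = intercept,
                 r_squared = r2, n_points = sum(keep),
                 excluded = names[!keep], fit_space = fit_space),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "power-law fit (%s space): y = 10^%.3f * x^%.3f, R^2 = %.4f, n = %d\n",
    x$fit_space, x$intercept, x$exponent, x$r_squared, x$n_points))
  if (length(x$excluded)) {
    cat("excluded (missing values):", paste(x$excluded, collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Acuity versus total-bundle regression across the packaged species
#'
#' Convenience wrapper for the headline cross-species relationship:
#' visual acuity (cycles/degree) as a power law in the estimated total
#' number of bundles in left V-1, across all packaged species, under a
#' chosen range policy and fit convention.
#'
#' @param table Species table (defaults to [load_species_table()]).
#' @param range_policy Passed to [derive_total_bundles()].
#' @param fit_space Passed to [powerlaw_fit()].
#' @return A `powerlaw_fit`.
#' @export
fit_acuity_vs_bundles <- function(table = load_species_table(),
                                  range_policy = c("midpoint", "low",
                                                   "high"),
                                  fit_space = c("log", "linear")) {
  range_policy <- match.arg(range_policy)
  fit_space <- match.arg(fit_space)
  tot <- derive_total_bundles(table, range_policy)
  powerlaw_fit(tot$total, table$acuity_cpd, names = table$species,
               fit_space = fit_space)
}
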