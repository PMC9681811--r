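#' Moment and normality summary of a distance sequence
#'
#' Sample mean, SD (n - 1 denominator), bias-adjusted standardized
#' skewness and excess kurtosis, and a Kolmogorov-Smirnov test against a
#' Gaussian with the sample's own mean and SD. The KS p-value uses the
#' asymptotic law without adjusting for the estimated parameters, which
#' inflates p relative to a Lilliefors-corrected test; published distance
#' tables report the naive statistic, and `lilliefors = TRUE` provides
#' the corrected alternative (Monte-Carlo, seeded internally).
#'
#' @param seq A [distance_sequence()] with at least 8 values.
#' @param lilliefors Use a Monte-Carlo Lilliefors p-value instead of the
#'   naive asymptotic one (default FALSE).
#' @return A list of class `distribution_summary` with `n`, `mean`, `sd`,
#'   `skewness`, `kurtosis` (excess), `ks_statistic`, `ks_p`.
#' @export
summarize_distances <- function(seq, lilliefors = FALSE) {
  stopifnot(inherits(seq, "distance_sequence"))
  x <- seq$values
  n <- length(x)
  if (n < 8) stop("summary needs at least 8 distances", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: all distances identical",
                   call. = FALSE)
  ks <- suppressWarnings(
    stats::ks.test(x, "pnorm", mean(x), s, exact = FALSE))
  ks_p <- ks$p.value
  if (lilliefors) {
    stat <- function(v) suppressWarnings(
      stats::ks.test(v, "pnorm", mean(v), stats::sd(v),
                     exact = FALSE)$statistic)
    null_d <- with_local_seed(20571, vapply(
      seq_len(500), function(i) stat(stats::rnorm(n)), 0))
    ks_p <- mean(null_d >= ks$statistic)
  }
  structure(list(n = n, mean = mean(x), sd = s,
                 skewness = e1071::skewness(x, type = 2),
                 kurtosis = e1071::kurtosis(x, type = 2),
                 ks_statistic = unname(ks$statistic), ks_p = ks_p),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "n = %d, mean = %.2f um, sd = %.2f um, skew = %.2f, ",
    "excess kurtosis = %.2f\nKS = %.3f, p = %.3g\n"),
    x$n, x$mean, x$sd, x$skewness, x$kurtosis, x$ks_statistic, x$ks_p))
  invisible(x)
}

#' Normalized histogram of inter-bundle distances
#'
#' Bins are left-closed, right-open and anchored at zero:
#' \[0, w), \[w, 2w), ... Frequencies sum to 1.
#'
#' @param seq A [distance_sequence()].
#' @param bin_width Bin width in micrometres (e.g. 5, or 10 for widely
#'   spaced bundles).
#' @return A data frame with columns `lower`, `upper`, `count`, `freq`.
#' @export
bin_histogram <- function(seq, bin_width) {
  stopifnot(inherits(seq, "distance_sequence"))
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  x <- seq$values
  bin <- floor(x / bin_width)
  nb <- max(bin) + 1L
  counts <- tabulate(bin + 1L, nbins = nb)
  data.frame(lower = (seq_len(nb) - 1L) * bin_width,
             upper = seq_len(nb) * bin_width,
             count = counts,
             freq = counts / length(x))
}

#' Two-sample location comparison of distance sequences
#'
#' `"mann_whitney"` (default) is the Mann-Whitney / Wilcoxon rank-sum
#' test: exact enumeration when both samples have at most 20 untied
#' values, otherwise the normal approximation with tie correction.
#' `"t_test"` is the unpaired Welch t-test.
#'
#' @param a,b [distance_sequence()] objects (or numeric vectors), each
#'   with at least 8 values.
#' @param method `"mann_whitney"` or `"t_test"`.
#' @return Two-sided p-value.
#' @export
compare_groups <- function(a, b, method = c("mann_whitney", "t_test")) {
  method <- match.arg(method)
  x <- if (inherits(a, "distance_sequence")) a$values else as.numeric(a)
  y <- if (inherits(b, "distance_sequence")) b$values else as.numeric(b)
  if (length(x) < 8 || length(y) < 8) {
    stop("each group needs at least 8 values", call. = FALSE)
  }
  if (stats::sd(c(x, y)) == 0) {
    stop("degenerate input: all values tied across both groups",
         call. = FALSE)
  }
  if (method == "mann_whitney") {
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- !ties && max(length(x), length(y)) <= 20
    suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value)
  } else {
    stats::t.test(x, y)$p.value
  }
}

#' Kruskal-Wallis comparison across several distance sequences
#'
#' One-way nonparametric ANOVA with tie-corrected H statistic and
#' chi-square p-value on k - 1 degrees of freedom. With only two groups
#' the result delegates to [compare_groups()].
#'
#' @param seqs List of [distance_sequence()] objects (or numeric
#'   vectors), each with at least 8 values.
#' @return p-value.
#' @export
kruskal_wallis_groups <- function(seqs) {
  vals <- lapply(seqs, function(s) {
    if (inherits(s, "distance_sequence")) s$values else as.numeric(s)
  })
  if (length(vals) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(vals, length, 0L) < 8)) {
    stop("each group needs at least 8 values", call. = FALSE)
  }
  if (length(vals) == 2) {
    return(compare_groups(vals[[1]], vals[[2]]))
  }
  stats::kruskal.test(vals)$p.value
}

#' Sequential-group scan along a traverse
#'
#' Splits the ordered sequence into consecutive, non-overlapping groups
#' of `group_size` bundles (the trailing remainder shorter than a full
#' group is dropped), reports each group's mean, SD and median in
#' traverse order, and tests each adjacent pair of groups. With
#' `method = "mann_whitney"` (default) medians are compared by rank-sum
#' test; `"t_test"` compares means; `"auto"` uses the t-test only when
#' both groups pass a KS normality screen at the 0.05 level and the
#' rank-sum test otherwise. Adjacent-pair p-values are reported raw by
#' default; `p_adjust = "holm"` applies a Holm correction.
#'
#' @param seq A [distance_sequence()] with at least `2 * group_size`
#'   values.
#' @param group_size Bundles per group (default 100).
#' @param method `"mann_whitney"`, `"t_test"` or `"auto"`.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return A list of class `group_scan` with `groups` (data frame:
#'   `group`, `n`, `mean`, `sd`, `median`), `p_values`, `tests`
#'   (test used per adjacent pair), `group_size`, `n_dropped`.
#' @export
sequential_groups <- function(seq, group_size = 100,
                              method = c("mann_whitney", "t_test", "auto"),
                              p_adjust = c("none", "holm")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(seq, "distance_sequence"))
  x <- seq$values
  k <- floor(length(x) / group_size)
  if (k < 2) {
    stop(sprintf("need at least %d values (2 groups of %d); got %d",
                 2 * group_size, group_size, length(x)), call. = FALSE)
  }
  groups <- lapply(seq_len(k), function(i) {
    x[((i - 1) * group_size + 1):(i * group_size)]
  })
  gstats <- data.frame(
    group = seq_len(k),
    n = group_size,
    mean = vapply(groups, mean, 0),
    sd = vapply(groups, stats::sd, 0),
    median = vapply(groups, stats::median, 0))
  is_normal <- function(g) {
    suppressWarnings(stats::ks.test(
      g, "pnorm", mean(g), stats::sd(g), exact = FALSE)$p.value) > 0.05
  }
  tests <- character(k - 1)
  p <- numeric(k - 1)
  for (i in seq_len(k - 1)) {
    use_t <- switch(method,
                    t_test = TRUE,
                    mann_whitney = FALSE,
                    auto = is_normal(groups[[i]]) &&
                           is_normal(groups[[i + 1]]))
    tests[i] <- if (use_t) "t_test" else "mann_whitney"
    p[i] <- compare_groups(groups[[i]], groups[[i + 1]],
                           method = tests[i])
  }
  if (p_adjust == "holm") p <- stats::p.adjust(p, "holm")
  structure(list(groups = gstats, p_values = p, tests = tests,
                 group_size = group_size,
                 n_dropped = length(x) - k * group_size),
            class = "group_scan")
}

#' @export
print.group_scan <- function(x, ...) {
  cat(sprintf("sequential group scan: %d groups of %d (%d trailing",
              nrow(x$groups), x$group_size, x$n_dropped),
      "values dropped)\n")
  print(x$groups, row.names = FALSE)
  cat("adjacent-pair p-values:\n")
  print(signif(x$p_values, 3))
  invisible(x)
}
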