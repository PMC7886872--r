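#' Per-segment percentage-point differences
#'
#' Elementwise absolute difference |simulated - observed| between two
#' per-segment percentage distributions covering the same segments.
#'
#' @param simulated,observed named percentage vectors over the same
#'   segment set, each summing to 100.
#' @return named vector of absolute differences, percentage points.
#' @export
pp_differences <- function(simulated, observed) {
  if (!setequal(names(simulated), names(observed)) ||
      is.null(names(simulated)))
    stop_input("simulated and observed must cover the same named segments")
  if (abs(sum(simulated) - 100) > 1e-6 || abs(sum(observed) - 100) > 1e-6)
    stop_input("each distribution must sum to 100")
  abs(simulated - as.numeric(observed[names(simulated)]))
}

#' Average percentage-point difference
#'
#' Arithmetic mean of the per-segment absolute differences — the headline
#' agreement summary between a simulated and a measured distribution.
#'
#' @param diffs vector of absolute differences ([pp_differences()]).
#' @return mean difference, percentage points.
#' @export
average_difference <- function(diffs) {
  if (length(diffs) < 1) stop_input("at least one segment required")
  mean(diffs)
}

# mid-ranks: average ranks for ties
mid_rank <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation (mid-ranks for ties)
#'
#' Pearson correlation of the mid-ranked data. Ties receive average ranks.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1].
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3)
    stop_input("a and b must have equal length >= 3")
  ra <- mid_rank(a); rb <- mid_rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0)
    stop_input("correlation undefined for a constant vector")
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

#' Bland-Altman agreement analysis
#'
#' Computes the paired differences d = a - b, their mean and sample
#' standard deviation (n - 1 denominator), the limits of agreement
#' `mean(d) +/- z sd(d)` (z = 1.96 for the 95% interval), and 95%
#' confidence intervals: for the mean, `mean +/- t sd/sqrt(n)`; for each
#' limit of agreement, `LoA +/- t sd sqrt(1/n + z^2 / (2(n-1)))`, with t
#' the 0.975 quantile of the t distribution on n - 1 degrees of freedom.
#'
#' @param a,b paired measurement vectors, equal length >= 2.
#' @param z limit-of-agreement multiplier (default 1.96).
#' @param conf confidence level for the intervals (default 0.95).
#' @return list of class `bland_altman`: `n`, `mean_difference`, `sd`,
#'   `loa_low`, `loa_high`, `ci_mean`, `ci_loa_low`, `ci_loa_high`,
#'   `means`, `differences`.
#' @export
bland_altman <- function(a, b, z = 1.96, conf = 0.95) {
  if (length(a) != length(b) || length(a) < 2)
    stop_input("a and b must have equal length >= 2")
  d <- a - b
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  se_loa <- s * sqrt(1 / n + z^2 / (2 * (n - 1)))
  structure(list(
    n = n, mean_difference = m, sd = s,
    loa_low = m - z * s, loa_high = m + z * s,
    ci_mean = c(m - tq * s / sqrt(n), m + tq * s / sqrt(n)),
    ci_loa_low = c(m - z * s - tq * se_loa, m - z * s + tq * se_loa),
    ci_loa_high = c(m + z * s - tq * se_loa, m + z * s + tq * se_loa),
    means = (a + b) / 2, differences = d),
    class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): mean difference %.3f, SD %.3f\n  LoA [%.3f, %.3f]\n  95%% CI mean [%.3f, %.3f], lower LoA [%.3f, %.3f], upper LoA [%.3f, %.3f]\n",
    x$n, x$mean_difference, x$sd, x$loa_low, x$loa_high,
    x$ci_mean[1], x$ci_mean[2], x$ci_loa_low[1], x$ci_loa_low[2],
    x$ci_loa_high[1], x$ci_loa_high[2]))
  invisible(x)
}

#' Full validation report for simulated vs observed distributions
#'
#' Bundles the per-segment absolute differences, their average, the
#' Spearman rank correlation and the Bland-Altman analysis of simulated
#' minus observed percentages.
#'
#' @param simulated,observed named percentage vectors over the same
#'   segments (each summing to 100).
#' @return list of class `validation_report`: `differences`,
#'   `average_difference`, `spearman_rho`, `bland_altman`.
#' @export
validate_distributions <- function(simulated, observed) {
  observed <- as.numeric(observed[names(simulated)]) |>
    stats::setNames(names(simulated))
  diffs <- pp_differences(simulated, observed)
  rho <- tryCatch(spearman_rho(simulated, observed),
                  error = function(e) NA_real_)
  structure(list(
    differences = diffs,
    average_difference = average_difference(diffs),
    spearman_rho = rho,
    bland_altman = bland_altman(as.numeric(simulated),
                                as.numeric(observed))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: average difference %.3f pp, Spearman rho %.4f\n",
              x$average_difference, x$spearman_rho))
  print(x$bland_altman)
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report a `validation_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_validation_json <- function(report, path) {
  ba <- report$bland_altman
  jsonlite::write_json(list(
    differences_pp = as.list(report$differences),
    average_difference_pp = report$average_difference,
    spearman_rho = report$spearman_rho,
    bland_altman = list(
      n = ba$n, mean_difference = ba$mean_difference, sd = ba$sd,
      loa_low = ba$loa_low, loa_high = ba$loa_high,
      ci_mean = ba$ci_mean, ci_loa_low = ba$ci_loa_low,
      ci_loa_high = ba$ci_loa_high)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Bland-Altman plot
#'
#' Base-graphics agreement plot: paired means against differences, solid
#' mean-difference line, dashed limits of agreement and error bars for the
#' confidence intervals of the mean and both limits.
#'
#' @param ba a [bland_altman()] result.
#' @param ... passed to [plot()].
#' @return `ba`, invisibly.
#' @export
plot_bland_altman <- function(ba, ...) {
  plot(ba$means, ba$differences,
       xlab = "Mean of paired values", ylab = "Difference", ...)
  graphics::abline(h = ba$mean_difference, col = "blue")
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  xr <- range(ba$means)
  xe <- xr[2] + 0.02 * diff(xr)
  for (ci in list(ba$ci_mean, ba$ci_loa_low, ba$ci_loa_high))
    graphics::arrows(xe, ci[1], xe, ci[2], angle = 90, code = 3,
                     length = 0.03)
  invisible(ba)
}
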