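# Repeatability/reproducibility correlation metrics: least-squares fit,
# Pearson r, Spearman rho (average-rank ties), mean absolute difference,
# percent nonlinearity, and five-number boxplot summaries.

#' Correlation analysis of matched measurement pairs
#'
#' Ordinary least squares of `y` on `x`, Pearson `r`, Spearman `rho`
#' (average ranks for ties), and the mean absolute difference
#' `mean(|y - x|)` between the paired measurements. When `group` labels are
#' supplied, the MAE between paired group means is also reported.
#'
#' @param x,y matched measurements (e.g. one operator vs the other), length
#'   >= 3 with non-zero variance in `x`.
#' @param group optional grouping labels (e.g. product) for the group-mean
#'   MAE.
#' @return An object of class `hsi_correlation`: `slope`, `intercept`,
#'   `pearson_r`, `spearman_rho`, `mean_abs_diff`, `mae_group_means`
#'   (`NA` without groups), `n`.
#' @export
correlate <- function(x, y, group = NULL) {
  if (length(x) != length(y)) stop_structural("x and y lengths differ")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop_validation("need at least 3 matched pairs")
  if (sd(x) == 0) stop_validation("x has zero variance; fit undefined")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  mae_gm <- NA_real_
  if (!is.null(group)) {
    group <- group[ok]
    mx <- tapply(x, group, mean)
    my <- tapply(y, group, mean)
    mae_gm <- mean(abs(my - mx))
  }
  structure(list(slope = slope, intercept = intercept,
                 pearson_r = cor(x, y),
                 spearman_rho = cor(x, y, method = "spearman"),
                 mean_abs_diff = mean(abs(y - x)),
                 mae_group_means = mae_gm,
                 n = length(x), x = x, y = y),
            class = "hsi_correlation")
}

#' @export
print.hsi_correlation <- function(x, ...) {
  cat(sprintf("slope %.3f, intercept %.3f, r = %.3f, rho = %.3f, mean|y-x| = %.3f (n = %d)\n",
              x$slope, x$intercept, x$pearson_r, x$spearman_rho,
              x$mean_abs_diff, x$n))
  invisible(x)
}

#' Percent nonlinearity of a measurement relationship
#'
#' `%NL = 100 * (delta_plus + |delta_minus|) / MaximumSignal`, where
#' `delta_plus` and `delta_minus` are the maximum positive and negative
#' residuals of the measurements about the least-squares line. The maximum
#' signal defaults to the largest absolute ordinate among the pairs (a
#' scale-invariant convention, recorded in the result).
#'
#' @param x,y matched measurements.
#' @param fit an [correlate()] result for the same pairs; computed if
#'   missing.
#' @param max_signal the denominator; defaults to `max(abs(y))`.
#' @return List with `percent_nl`, `delta_plus`, `delta_minus` (reported
#'   <= 0), `max_signal`.
#' @export
percent_nonlinearity <- function(x, y, fit = NULL, max_signal = NULL) {
  if (is.null(fit)) fit <- correlate(x, y)
  res <- y - (fit$intercept + fit$slope * x)
  if (is.null(max_signal)) max_signal <- max(abs(y))
  if (max_signal == 0) stop_validation("maximum signal is zero; %%NL undefined")
  dp <- max(res); dm <- min(res)
  list(percent_nl = 100 * (dp + abs(dm)) / max_signal,
       delta_plus = dp, delta_minus = dm, max_signal = max_signal)
}

#' Five-number boxplot summary
#'
#' Quartiles by linear interpolation (`quantile` type 7); whiskers extend to
#' the most extreme data points within `1.5 * (Q3 - Q1)` beyond the box;
#' points beyond the whiskers are outliers.
#'
#' @param samples numeric vector, `n >= 1`.
#' @return An object of class `boxplot_summary` with `q1`, `median`, `q3`,
#'   `mean`, `whisker_low`, `whisker_high`, `outliers`, `n`.
#' @export
boxplot_summary <- function(samples) {
  samples <- samples[is.finite(samples)]
  if (length(samples) < 1) stop_validation("need at least one sample")
  qs <- quantile(samples, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo_fence <- qs[1] - 1.5 * iqr
  hi_fence <- qs[3] + 1.5 * iqr
  inside <- samples >= lo_fence & samples <= hi_fence
  structure(list(q1 = qs[1], median = qs[2], q3 = qs[3],
                 mean = mean(samples),
                 whisker_low = min(samples[inside]),
                 whisker_high = max(samples[inside]),
                 outliers = sort(samples[!inside]),
                 n = length(samples)),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf("boxplot: [%.3g | %.3g %.3g %.3g | %.3g], mean %.3g, %d outlier(s)\n",
              x$whisker_low, x$q1, x$median, x$q3, x$whisker_high, x$mean,
              length(x$outliers)))
  invisible(x)
}
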