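#' Plot the monthly first-time post series
#'
#' Column chart of monthly first-time posts with exact Poisson 95% error
#' bars.
#'
#' @param series A [first_time_post_series()] tibble.
#' @return A ggplot object.
#' @export
plot_first_time_posts <- function(series) {
  require_ggplot()
  ggplot2::ggplot(series, ggplot2::aes(x = month, y = n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 10) +
    ggplot2::labs(x = NULL, y = "First-time posts",
                  title = "First-time posts by month") +
    ggplot2::theme_minimal()
}

#' Plot weekly-adjusted day-of-week means
#'
#' @param fit A [weekday_adjusted_means()] result.
#' @return A ggplot object.
#' @export
plot_weekday_means <- function(fit) {
  require_ggplot()
  stopifnot(inherits(fit, "weekday_fit"))
  ggplot2::ggplot(fit$estimates,
                  ggplot2::aes(x = weekday, y = estimate)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = ci_low, ymax = ci_high),
                           width = 0.3) +
    ggplot2::labs(x = NULL, y = "Mean items per day",
                  title = "Items per weekday, adjusted for weekly variation") +
    ggplot2::theme_minimal()
}

#' Plot the cumulative activity distribution
#'
#' @param curve A [cumulative_activity_curve()] tibble.
#' @return A ggplot object.
#' @export
plot_cumulative_activity <- function(curve) {
  require_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(x = user_frac, y = item_frac)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Share of users (most active first)",
                  y = "Cumulative share of items",
                  title = "Cumulative distribution of user activity") +
    ggplot2::theme_minimal()
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
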