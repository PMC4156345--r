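#' Daily total-item count series
#'
#' One row per calendar day of the coverage interval (days without
#' activity get 0), with the ISO-8601 week key (Monday start) used for
#' weekly clustering and the weekday.
#'
#' @param s An [interaction_set].
#' @param start,end Coverage bounds; default to the set's period.
#' @return A tibble with `date`, `n`, `iso_week` (e.g. `"2012-W07"`),
#'   `weekday` (factor, Monday first).
#' @export
daily_count_series <- function(s, start = s$period_start,
                               end = s$period_end) {
  stopifnot(inherits(s, "interaction_set"))
  tz <- attr_tz(s$items$timestamp)
  dates <- seq(as.Date(start), as.Date(end), by = "day")
  counts <- table(factor(as.character(as.Date(s$items$timestamp, tz = tz)),
                         levels = as.character(dates)))
  tibble::tibble(
    date = dates,
    n = as.integer(counts),
    iso_week = strftime(dates, "%G-W%V"),
    weekday = weekday_factor(dates))
}

weekday_factor <- function(dates) {
  lv <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
  factor(lv[as.integer(format(dates, "%u"))], levels = lv)
}

#' Exact (Garwood) Poisson confidence interval for counts
#'
#' Chi-square quantile form: for an observed count k, the lower bound is
#' `qchisq(alpha/2, 2k)/2` (0 when k = 0) and the upper bound is
#' `qchisq(1 - alpha/2, 2k + 2)/2`. Exact rather than normal-approximate,
#' so small monthly counts are covered correctly.
#'
#' @param k Nonnegative integer count(s).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `k`, `ci_low`, `ci_high`.
#' @export
garwood_ci <- function(k, conf_level = 0.95) {
  stopifnot(all(k >= 0))
  alpha <- 1 - conf_level
  low <- ifelse(k == 0, 0, qchisq(alpha / 2, 2 * k) / 2)
  high <- qchisq(1 - alpha / 2, 2 * k + 2) / 2
  tibble::tibble(k = as.integer(k), ci_low = low, ci_high = high)
}

#' Monthly series of first-time posts with exact Poisson intervals
#'
#' A first-time post is the first blog post a user account ever makes
#' (determined over the full history carried by the timelines, so repeat
#' posters arriving from before the analysis period are not counted
#' again). Counts are aggregated by calendar month over the set's period;
#' every month appears, zero months included, with Garwood 95% intervals.
#'
#' @param s An [interaction_set].
#' @param timelines A [build_timelines()] result supplying
#'   `first_post_date`.
#' @param conf_level Confidence level for the intervals.
#' @return A tibble with `month` (first day of month), `n`, `ci_low`,
#'   `ci_high`.
#' @export
first_time_post_series <- function(s, timelines, conf_level = 0.95) {
  stopifnot(inherits(s, "interaction_set"),
            inherits(timelines, "user_timelines"))
  fp <- timelines$users$first_post_date
  fp <- fp[!is.na(fp) & fp >= s$period_start & fp <= s$period_end]
  months <- seq(as.Date(format(s$period_start, "%Y-%m-01")),
                as.Date(format(s$period_end, "%Y-%m-01")), by = "month")
  key <- format(fp, "%Y-%m-01")
  counts <- table(factor(key, levels = as.character(months)))
  ci <- garwood_ci(as.integer(counts), conf_level)
  tibble::tibble(month = months, n = as.integer(counts),
                 ci_low = ci$ci_low, ci_high = ci$ci_high)
}

#' Drop ISO weeks containing a business-day event
#'
#' Removes every ISO week in which a supplied event date (public holiday,
#' awareness day) falls on a normal business day (Monday-Friday); events
#' falling on a weekend exclude nothing, since they do not disturb the
#' working-week posting pattern.
#'
#' @param series A [daily_count_series()] tibble.
#' @param events Event dates (`Date` or ISO strings); see
#'   [read_holidays()] for the bundled calendar.
#' @return The filtered series, with the excluded week keys in
#'   `attr(, "excluded_weeks")`.
#' @export
exclude_event_weeks <- function(series, events) {
  events <- as.Date(events)
  busy <- events[as.integer(format(events, "%u")) <= 5]
  excl <- unique(strftime(busy, "%G-W%V"))
  excl <- intersect(excl, unique(series$iso_week))
  out <- series[!series$iso_week %in% excl, , drop = FALSE]
  attr(out, "excluded_weeks") <- excl
  out
}

#' Day-of-week activity means adjusted for weekly clustering
#'
#' Estimating-equation model of total daily items on weekday: saturated
#' weekday factor, identity link, Poisson working variance, independence
#' working correlation, with sandwich (cluster-robust) standard errors
#' over ISO weeks to allow for non-independence of posting levels within
#' a week. Under this specification the point estimates are exactly the
#' per-weekday arithmetic means of the daily totals, which keeps the
#' adjusted means directly interpretable; only the uncertainty is
#' adjusted for weekly clustering. Contrasts against Monday are Wald z
#' tests on the robust covariance.
#'
#' @param series A [daily_count_series()] tibble, typically after
#'   [exclude_event_weeks()].
#' @param conf_level Confidence level for the interval columns.
#' @return An object of class `weekday_fit`: a list with `estimates`
#'   (tibble: `weekday`, `estimate`, `ci_low`, `ci_high`,
#'   `diff_vs_monday`, `z`, `p_value`), `n_weeks`, `excluded_weeks`.
#' @export
weekday_adjusted_means <- function(series, conf_level = 0.95) {
  stopifnot(all(c("date", "n", "iso_week", "weekday") %in% names(series)))
  if (length(unique(series$iso_week)) < 2) {
    stop("need at least 2 weeks of data after exclusion", call. = FALSE)
  }
  present <- table(series$weekday)
  if (any(present == 0)) {
    stop("weekday absent from all included weeks: ",
         paste(names(present)[present == 0], collapse = ", "),
         call. = FALSE)
  }
  means <- tapply(series$n, series$weekday, mean)
  fit <- glm(n ~ 0 + weekday, data = series,
             family = quasipoisson(link = "identity"),
             start = as.numeric(means))
  V <- sandwich::vcovCL(fit, cluster = series$iso_week, type = "HC0")
  est <- coef(fit)
  names(est) <- sub("^weekday", "", names(est))
  rownames(V) <- colnames(V) <- names(est)
  se <- sqrt(diag(V))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  lv <- levels(series$weekday)
  dmon <- est[lv] - est["Mon"]
  se_d <- vapply(lv, function(d) {
    if (d == "Mon") return(0)
    sqrt(V[d, d] + V["Mon", "Mon"] - 2 * V[d, "Mon"])
  }, numeric(1))
  z <- ifelse(se_d == 0, 0, dmon / se_d)
  out <- tibble::tibble(
    weekday = factor(lv, levels = lv),
    estimate = unname(est[lv]),
    ci_low = unname(est[lv] - zq * se[lv]),
    ci_high = unname(est[lv] + zq * se[lv]),
    diff_vs_monday = unname(dmon),
    z = unname(z),
    p_value = ifelse(lv == "Mon", NA_real_, unname(2 * pnorm(-abs(z)))))
  structure(list(estimates = out,
                 n_weeks = length(unique(series$iso_week)),
                 excluded_weeks = attr(series, "excluded_weeks") %||%
                   character()),
            class = "weekday_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.weekday_fit <- function(x, ...) {
  cat(sprintf("<weekday_fit> %d weeks (%d excluded)\n", x$n_weeks,
              length(x$excluded_weeks)))
  print(x$estimates)
  invisible(x)
}
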